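# Formats: canonical JSON map documents (schema "agromap-map/1"), GeoJSON
# plot input, DOT graph export, pattern documents. Serialization is
# canonical (darts and faces by id, property keys sorted) so equal maps
# serialize byte-identically.

MAP_SCHEMA <- "agromap-map/1"

sorted_props <- function(p) {
  if (length(p) == 0) return(stats::setNames(list(), character(0)))
  p[order(names(p))]
}

#' Serialize a map to its canonical JSON document
#'
#' Lossless: beta tables, coordinates, dart properties, face records, holes,
#' hierarchy and georeferencing all round-trip through [parse_map()].
#' Output is byte-stable: serializing twice, or serializing a [copy_map()],
#' gives identical strings.
#'
#' @param m A closed `cmap2` map.
#' @return A JSON string (class `json`).
#' @export
serialize_map <- function(m) {
  ids <- darts(m)
  dart_list <- lapply(ids, function(d) {
    list(id = d,
         beta1 = if (is.na(m$b1[d])) NULL else m$b1[d],
         beta2 = if (is.na(m$b2[d])) NULL else m$b2[d],
         x = m$x[d], y = m$y[d],
         properties = sorted_props(m$props[[d]]),
         face = if (is.na(m$face_of[d])) NULL else m$face_of[d],
         hole_of = if (is.na(m$hole_of[d])) NULL else m$hole_of[d])
  })
  fids <- faces(m)
  face_list <- lapply(fids, function(f) {
    rec <- get_face(m, f)
    list(id = rec$id, anchor = rec$anchor,
         element_type = if (is.na(rec$element_type)) NULL else rec$element_type,
         attributes = sorted_props(rec$attributes),
         holes = lapply(rec$holes, function(h)
           list(anchor = h$anchor, child = h$child)),
         parent = if (is.na(rec$parent)) NULL else rec$parent,
         provisional = rec$provisional)
  })
  doc <- list(version = MAP_SCHEMA, darts = dart_list, faces = face_list,
              georef = m$georef)
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname serialize_map
#' @param path File path to write to / read from.
#' @export
write_map <- function(m, path) {
  writeLines(as.character(serialize_map(m)), path)
  invisible(path)
}

#' Parse a canonical JSON map document
#'
#' The parsed map is validated; inconsistent beta tables are refused with an
#' error naming the violated rule.
#'
#' @param txt JSON string (or use `read_map(path)`).
#' @return A closed `cmap2` map.
#' @export
parse_map <- function(txt) {
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!identical(doc$version, MAP_SCHEMA))
    stop(sprintf("unsupported map document version: %s", doc$version), call. = FALSE)
  m <- cmap()
  nmax <- max(vapply(doc$darts, function(d) as.integer(d$id), integer(1)), 0L)
  m$n_created <- nmax
  m$b1 <- rep(NA_integer_, nmax); m$b2 <- rep(NA_integer_, nmax)
  m$x <- rep(NA_real_, nmax); m$y <- rep(NA_real_, nmax)
  m$alive <- rep(FALSE, nmax)
  m$props <- vector("list", nmax)
  m$face_of <- rep(NA_integer_, nmax); m$hole_of <- rep(NA_integer_, nmax)
  for (d in doc$darts) {
    id <- as.integer(d$id)
    m$alive[id] <- TRUE
    m$b1[id] <- if (is.null(d$beta1)) NA_integer_ else as.integer(d$beta1)
    m$b2[id] <- if (is.null(d$beta2)) NA_integer_ else as.integer(d$beta2)
    m$x[id] <- as.numeric(d$x); m$y[id] <- as.numeric(d$y)
    m$props[[id]] <- d$properties
    m$face_of[id] <- if (is.null(d$face)) NA_integer_ else as.integer(d$face)
    m$hole_of[id] <- if (is.null(d$hole_of)) NA_integer_ else as.integer(d$hole_of)
  }
  for (f in doc$faces) {
    new_face(m, anchor = as.integer(f$anchor),
             element_type = if (is.null(f$element_type)) NA_character_ else f$element_type,
             attributes = f$attributes,
             parent = if (is.null(f$parent)) NA_integer_ else as.integer(f$parent),
             provisional = isTRUE(f$provisional),
             id = as.integer(f$id))
    if (length(f$holes))
      m$faces[[as.character(f$id)]]$holes <- lapply(f$holes, function(h)
        list(anchor = as.integer(h$anchor), child = as.integer(h$child)))
  }
  m$georef <- doc$georef
  rep <- validate_map(m)
  if (!rep$ok) {
    rules <- vapply(rep$violations, function(v) v$rule, character(1))
    stop(sprintf("inconsistent map document: %s", paste(rules, collapse = ", ")),
         call. = FALSE)
  }
  m
}

#' @rdname parse_map
#' @param path File path.
#' @export
read_map <- function(path) parse_map(paste(readLines(path, warn = FALSE), collapse = "\n"))

# GeoJSON --------------------------------------------------------------------

#' Read a plot specification from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features. Each feature's
#' `properties` must carry `element_type`; `id` and `parent_id` are optional
#' (features are numbered in order when `id` is absent). Coordinates are
#' shifted to plot-local metres with the first point of the first feature as
#' origin; the shift is stored as an identity-scale affine in the plot spec's
#' `georef`.
#'
#' @param path Path to a GeoJSON file.
#' @return A [plot_spec()].
#' @export
read_geojson <- function(path) {
  doc <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"),
                            simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection"))
    stop("GeoJSON input must be a FeatureCollection", call. = FALSE)
  origin <- NULL
  areas <- list()
  for (k in seq_along(doc$features)) {
    ft <- doc$features[[k]]
    props <- ft$properties
    fid <- if (!is.null(props$id)) as.character(props$id) else
      if (!is.null(ft$id)) as.character(ft$id) else sprintf("feature%d", k)
    gtype <- ft$geometry$type
    if (!identical(gtype, "Polygon"))
      stop(sprintf("feature '%s': geometry must be Polygon, got %s", fid,
                   if (is.null(gtype)) "none" else gtype), call. = FALSE)
    if (is.null(props$element_type))
      stop(sprintf("feature '%s': missing element_type property", fid), call. = FALSE)
    ring <- ft$geometry$coordinates[[1]]
    pts <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (is.null(origin)) origin <- pts[1, ]
    pts <- sweep(pts, 2, origin)
    extra <- props[setdiff(names(props), c("id", "parent_id", "element_type"))]
    areas[[length(areas) + 1L]] <- plot_area(
      fid, dedup_poly(pts), props$element_type, as.list(extra),
      parent = if (is.null(props$parent_id)) NA_character_ else
        as.character(props$parent_id))
  }
  ids <- vapply(areas, function(a) a$id, character(1))
  for (a in areas)
    if (!is.na(a$parent) && !(a$parent %in% ids))
      stop(sprintf("area '%s': unresolved parent_id '%s'", a$id, a$parent),
           call. = FALSE)
  plot_spec(areas, georef = list(origin = as.numeric(origin),
                                 scale = c(1, 1), units = "m"))
}

#' Write a plot specification to GeoJSON
#'
#' @param spec A [plot_spec()].
#' @param path Output path.
#' @export
write_geojson <- function(spec, path) {
  origin <- if (!is.null(spec$georef$origin)) spec$georef$origin else c(0, 0)
  feats <- lapply(spec$areas, function(a) {
    ring <- rbind(a$polygon, a$polygon[1, , drop = FALSE])
    ring <- sweep(ring, 2, -origin)
    list(type = "Feature",
         properties = c(list(id = a$id, element_type = a$element_type),
                        if (!is.na(a$parent)) list(parent_id = a$parent),
                        sorted_props(a$attributes)),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)), function(i)
                           as.numeric(ring[i, ])))))
  })
  doc <- list(type = "FeatureCollection", features = feats)
  writeLines(as.character(
    jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")), path)
  invisible(path)
}

# DOT ------------------------------------------------------------------------

#' Export a map (or its dual) as a DOT graph
#'
#' For a primal map: one DOT node per map vertex (labelled with its
#' coordinates), one directed edge per dart, or one undirected edge per
#' beta2 pair with `collapse = TRUE`. For a map built by [build_dual()]:
#' one node per primal face labelled with its element type and placed at the
#' face centroid, one edge per dart / edge pair.
#'
#' @param m A closed `cmap2` map (primal or a [build_dual()] result).
#' @param path Output path.
#' @param collapse Emit one undirected edge per beta2 pair.
#' @export
export_dot <- function(m, path, collapse = FALSE) {
  if (n_darts(m) == 0) stop("cannot export an empty map", call. = FALSE)
  node_of_attr <- attr(m, "node_of")
  lines <- c("digraph agromap {")
  if (!is.null(node_of_attr)) {
    placement <- attr(m, "placement")
    labels <- attr(m, "node_label")
    fids <- sort(unique(as.integer(node_of_attr)))
    for (f in fids) {
      ctr <- placement[[as.character(f)]]
      lab <- labels[[as.character(f)]]
      if (is.null(lab)) lab <- f
      lines <- c(lines, sprintf('  f%s [label="%s", pos="%.3f,%.3f!"];',
                                f, lab, ctr[1], ctr[2]))
    }
    ids <- sort(darts(m))
    emitted <- integer(0)
    for (d in ids) {
      e <- m$b2[d]
      if (collapse && e %in% emitted) next
      a <- node_of_attr[[as.character(d)]]
      b <- node_of_attr[[as.character(e)]]
      lines <- c(lines, sprintf("  f%s -> f%s%s;", a, b,
                                if (collapse) " [dir=none]" else sprintf(' [label="%d"]', d)))
      emitted <- c(emitted, d)
    }
  } else {
    vorbs <- vertex_orbits(m)
    vid <- integer(m$n_created)
    for (k in seq_along(vorbs)) vid[vorbs[[k]]] <- k
    for (k in seq_along(vorbs)) {
      d0 <- vorbs[[k]][1]
      lines <- c(lines, sprintf('  v%d [label="(%.2f, %.2f)", pos="%.3f,%.3f!"];',
                                k, m$x[d0], m$y[d0], m$x[d0], m$y[d0]))
    }
    ids <- sort(darts(m))
    emitted <- integer(0)
    for (d in ids) {
      e <- m$b2[d]
      if (collapse && e %in% emitted) next
      lines <- c(lines, sprintf("  v%d -> v%d%s;", vid[d], vid[e],
                                if (collapse) " [dir=none]" else sprintf(' [label="%d"]', d)))
      emitted <- c(emitted, d)
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

# Patterns -------------------------------------------------------------------

#' Read / write a pattern document
#'
#' A pattern document is JSON with fields `fragment` (a canonical map
#' document), `roles` (face id -> role) and `predicates`.
#'
#' @param path File path.
#' @export
read_pattern <- function(path) {
  doc <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"),
                            simplifyVector = FALSE)
  frag <- parse_map(jsonlite::toJSON(doc$fragment, auto_unbox = TRUE, digits = NA,
                                     null = "null"))
  roles <- unlist(doc$roles)
  pattern(frag, roles, predicates = doc$predicates)
}

#' @rdname read_pattern
#' @param pat An [pattern()] object.
#' @export
write_pattern <- function(pat, path) {
  doc <- list(fragment = jsonlite::fromJSON(serialize_map(pat$fragment),
                                            simplifyVector = FALSE),
              roles = as.list(pat$roles),
              predicates = pat$predicates)
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                           null = "null")), path)
  invisible(path)
}
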
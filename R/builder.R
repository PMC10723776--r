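# Incremental construction of a closed plot map from polygons. Each area
# becomes a face; coincident borders are beta2-sewn during merging; embedded
# elements (trees inside an understory strip) become holes; the unbounded
# complement becomes the explicit outside face.
#
# Orientation convention: interior faces are counterclockwise (the interior
# lies on the left of every dart), the provisional complement / outside face
# and hole cycles are clockwise.

#' Declarative plot specification
#'
#' A plot spec is a list of areas: simple polygons in plot-local metres with
#' an element type, free attributes, and an optional parent (for embedded
#' elements such as trees inside a strip).
#'
#' @param areas List of areas, each created by [plot_area()].
#' @param georef Optional affine georeferencing metadata (stored, never used
#'   in topology).
#' @return An object of class `plot_spec`.
#' @export
plot_spec <- function(areas, georef = NULL) {
  stopifnot(is.list(areas))
  ids <- vapply(areas, function(a) a$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate area ids in plot spec", call. = FALSE)
  structure(list(areas = areas, georef = georef), class = "plot_spec")
}

#' @rdname plot_spec
#' @param id Area identifier (string).
#' @param polygon Two-column matrix of vertices (metres), any orientation.
#' @param element_type One of `"tree"`, `"crop"`, `"understory_strip"`,
#'   `"mixed"`.
#' @param attributes Named list of free attributes (species, planting date,
#'   crown radius, ...).
#' @param parent Parent area id, or NA for a top-level area.
#' @export
plot_area <- function(id, polygon, element_type,
                      attributes = list(), parent = NA_character_) {
  element_type <- match.arg(element_type,
                            c("tree", "crop", "understory_strip", "mixed"))
  polygon <- dedup_poly(polygon)
  list(id = as.character(id), polygon = polygon, element_type = element_type,
       attributes = attributes, parent = as.character(parent))
}

#' @export
print.plot_spec <- function(x, ...) {
  top <- sum(vapply(x$areas, function(a) is.na(a$parent), logical(1)))
  cat(sprintf("<plot_spec: %d areas (%d top-level)>\n", length(x$areas), top))
  invisible(x)
}

#' Build a one-face map fragment from a polygon
#'
#' Creates 2k darts for a k-vertex polygon: a counterclockwise inner beta1
#' cycle carrying the face, and a clockwise outer cycle (the provisional
#' complement), beta2-sewn pairwise. The fragment is a closed map in its own
#' right; the complement is later consumed by [merge_maps()],
#' [embed_hole()] or [make_border_explicit()].
#'
#' @param vertices Two-column matrix of polygon vertices (>= 3, simple);
#'   orientation is normalized to counterclockwise.
#' @param element_type Element type of the face.
#' @param attributes Named list of face attributes.
#' @param map Optionally an existing map to create the fragment in.
#' @return The map, with attribute bookkeeping in `$faces`; the interior
#'   face id is in `attr(, "face_id")` of the returned map's last fragment
#'   (use [faces()] to query).
#' @export
face_from_polygon <- function(vertices, element_type, attributes = list(),
                              map = NULL) {
  poly <- dedup_poly(vertices)
  if (nrow(poly) < 3) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  if (!is_simple_polygon(poly)) stop("polygon is not simple", call. = FALSE)
  if (signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  m <- if (is.null(map)) cmap() else map
  k <- nrow(poly)
  nxt <- function(i) if (i == k) 1L else i + 1L
  inner <- integer(k); outer <- integer(k)
  for (i in seq_len(k))
    inner[i] <- add_dart(m, poly[i, 1], poly[i, 2],
                         list(element_type = element_type))
  for (i in seq_len(k))
    outer[i] <- add_dart(m, poly[nxt(i), 1], poly[nxt(i), 2], list())
  for (i in seq_len(k)) {
    link1(m, inner[i], inner[nxt(i)])
    link1(m, outer[i], outer[if (i == 1L) k else i - 1L])
    sew2(m, inner[i], outer[i])
  }
  fid <- new_face(m, anchor = inner[1], element_type = element_type,
                  attributes = attributes)
  cid <- new_face(m, anchor = outer[1], element_type = NA_character_,
                  provisional = TRUE)
  m$face_of[inner] <- fid
  m$face_of[outer] <- cid
  m$closed <- FALSE
  attr(m, "face_id") <- fid
  m
}

provisional_faces <- function(m) {
  ids <- vapply(m$faces, function(f) f$id, integer(1))
  unname(ids[vapply(m$faces, function(f) isTRUE(f$provisional), logical(1))])
}

# head node of a dart: origin of its beta2 partner when sewn, else of its
# beta1 successor.
dart_head <- function(m, d) {
  p <- m$b2[d]
  if (is.na(p)) p <- m$b1[d]
  if (is.na(p)) stop(sprintf("dart %d has no set link to infer its head", d),
                     call. = FALSE)
  c(m$x[p], m$y[p])
}

same_pt <- function(p, q, tol) max(abs(p - q)) <= tol

#' Merge two maps along their coincident borders
#'
#' Imports the darts of `b` into `a` (ids renumbered consecutively), then for
#' every pair of geometrically coincident, oppositely oriented complement
#' edges deletes the two complement darts and beta2-sews the two interior
#' darts. The surviving complement cycles are re-stitched so exactly one
#' provisional complement remains. Shared borders must consist of whole
#' edges (edge-to-edge conformity); partial overlaps raise an error.
#'
#' @param a Accumulating `cmap2` map (modified in place and returned).
#' @param b Map fragment to merge in (not usable afterwards).
#' @return `a`.
#' @export
merge_maps <- function(a, b) {
  if (n_darts(b) == 0) return(invisible(a))
  if (n_darts(a) == 0) return(invisible(b))
  tol <- a$tol
  off <- a$n_created
  foff <- a$next_face - 1L
  bids <- darts(b)
  idmap <- integer(b$n_created)
  for (d in bids) {
    nd <- add_dart(a, b$x[d], b$y[d], b$props[[d]])
    idmap[d] <- nd
  }
  for (d in bids) {
    if (!is.na(b$b1[d])) a$b1[idmap[d]] <- idmap[b$b1[d]]
    if (!is.na(b$b2[d])) a$b2[idmap[d]] <- idmap[b$b2[d]]
  }
  new_bfaces <- integer(0)
  for (frec in b$faces) {
    nid <- new_face(a, anchor = idmap[frec$anchor],
                    element_type = frec$element_type,
                    attributes = frec$attributes,
                    parent = if (is.na(frec$parent)) NA_integer_ else frec$parent + foff,
                    provisional = frec$provisional)
    # new_face allocates sequentially; remap darts belonging to this face
    sel <- bids[!is.na(b$face_of[bids]) & b$face_of[bids] == frec$id]
    a$face_of[idmap[sel]] <- nid
    selh <- bids[!is.na(b$hole_of[bids]) & b$hole_of[bids] == frec$id]
    if (length(selh)) a$hole_of[idmap[selh]] <- nid
    if (length(frec$holes))
      a$faces[[as.character(nid)]]$holes <- lapply(frec$holes, function(h)
        list(anchor = idmap[h$anchor], child = h$child + foff))
    new_bfaces <- c(new_bfaces, nid)
  }
  # locate complement darts on both sides
  prov <- provisional_faces(a)
  comp_a <- setdiff(prov, new_bfaces)
  comp_b <- intersect(prov, new_bfaces)
  if (length(comp_a) != 1L || length(comp_b) != 1L)
    stop("merge_maps: each map must carry exactly one provisional complement",
         call. = FALSE)
  ca_darts <- darts(a)[!is.na(a$face_of[darts(a)]) & a$face_of[darts(a)] == comp_a]
  cb_darts <- darts(a)[!is.na(a$face_of[darts(a)]) & a$face_of[darts(a)] == comp_b]
  seg <- function(d) list(o = c(a$x[d], a$y[d]), h = dart_head(a, d))
  matched <- list()
  used_b <- rep(FALSE, length(cb_darts))
  for (da in ca_darts) {
    sa <- seg(da)
    for (k in seq_along(cb_darts)) {
      if (used_b[k]) next
      sb <- seg(cb_darts[k])
      if (same_pt(sa$o, sb$h, tol) && same_pt(sa$h, sb$o, tol)) {
        matched[[length(matched) + 1L]] <- c(da, cb_darts[k])
        used_b[k] <- TRUE
        break
      }
    }
  }
  # conformity check: an endpoint of one side lying strictly inside an edge
  # of the other side means a T-junction
  check_conform <- function(cd, other) {
    for (d in cd) {
      s <- seg(d)
      for (e in other) {
        t <- seg(e)
        for (p in list(t$o, t$h)) {
          if (same_pt(p, s$o, tol) || same_pt(p, s$h, tol)) next
          if (on_segment(p, s$o, s$h, tol))
            stop("non-conforming borders (T-junction between merged areas)",
                 call. = FALSE)
        }
      }
    }
  }
  check_conform(ca_darts, cb_darts)
  check_conform(cb_darts, ca_darts)
  if (length(matched) == 0)
    stop("merge_maps: maps share no conforming border edge", call. = FALSE)
  for (pr in matched) {
    ia <- a$b2[pr[1]]; ib <- a$b2[pr[2]]
    remove_dart(a, pr[1]); remove_dart(a, pr[2])
    sew2(a, ia, ib)
  }
  # remaining complement darts of both cycles form the union boundary;
  # re-stitch their beta1 chain by walking node coincidence
  rem <- c(setdiff(ca_darts, vapply(matched, `[`, integer(1), 1L)),
           setdiff(cb_darts, vapply(matched, `[`, integer(1), 2L)))
  if (length(rem)) {
    origins <- dart_origin(a, rem)
    for (d in rem) {
      h <- dart_head(a, d)
      cand <- rem[abs(origins[, 1] - h[1]) <= tol & abs(origins[, 2] - h[2]) <= tol]
      if (length(cand) != 1L)
        stop("non-conforming borders (ambiguous outer boundary)", call. = FALSE)
      a$b1[d] <- cand
    }
    a$face_of[rem] <- comp_a
    a$faces[[as.character(comp_a)]]$anchor <- rem[1]
    a$faces[[as.character(comp_b)]] <- NULL
  } else {
    stop("merge_maps: merged maps have no outer boundary left", call. = FALSE)
  }
  invisible(a)
}

#' Embed a child fragment as a hole of a face
#'
#' The child's provisional complement cycle becomes a clockwise hole cycle of
#' the parent face, beta2-sewn to the child's border darts; the hierarchy is
#' queryable through [face_holes()] and [face_parent()]. The child polygon
#' must lie strictly inside the parent's boundary and clear of existing
#' holes.
#'
#' @param m Map containing the parent face (modified in place).
#' @param parent Parent face id.
#' @param child A one-face fragment from [face_from_polygon()].
#' @return The embedded face id.
#' @export
embed_hole <- function(m, parent, child) {
  prec <- get_face(m, parent)
  ppoly <- face_polygon(m, parent)
  cface <- attr(child, "face_id")
  cpoly <- face_polygon(child, cface)
  if (!poly_strictly_inside(cpoly, ppoly))
    stop("embedded element must lie strictly inside its parent face", call. = FALSE)
  for (h in face_holes(m, parent)) {
    if (polys_overlap(cpoly, face_polygon(m, h)))
      stop("embedded element overlaps an existing hole", call. = FALSE)
  }
  off <- m$n_created
  child_prov <- provisional_faces(child)
  stopifnot(length(child_prov) == 1L)
  idmap <- integer(child$n_created)
  for (d in darts(child)) idmap[d] <- add_dart(m, child$x[d], child$y[d], child$props[[d]])
  for (d in darts(child)) {
    if (!is.na(child$b1[d])) m$b1[idmap[d]] <- idmap[child$b1[d]]
    if (!is.na(child$b2[d])) m$b2[idmap[d]] <- idmap[child$b2[d]]
  }
  crec <- get_face(child, cface)
  nid <- new_face(m, anchor = idmap[crec$anchor], element_type = crec$element_type,
                  attributes = crec$attributes, parent = parent)
  cdarts <- darts(child)
  sel <- cdarts[child$face_of[cdarts] == cface]
  m$face_of[idmap[sel]] <- nid
  holed <- cdarts[child$face_of[cdarts] == child_prov]
  hole_ids <- idmap[holed]
  m$face_of[hole_ids] <- prec$id
  m$hole_of[hole_ids] <- nid
  for (d in hole_ids) m$props[[d]]$element_type <- prec$element_type
  m$faces[[as.character(parent)]]$holes <-
    c(m$faces[[as.character(parent)]]$holes,
      list(list(anchor = hole_ids[1], child = nid)))
  m$closed <- FALSE
  invisible(nid)
}

#' Make the external border explicit
#'
#' On a map built from polygon fragments, the single surviving provisional
#' complement cycle is promoted to the outside face. On a raw kernel map with
#' unsewn darts (the open two-triangle state), one new dart is created per
#' unsewn border dart and linked into the outside cycle. Already-closed maps
#' are returned unchanged.
#'
#' @param m A `cmap2` map (modified in place).
#' @return `m`, now closed with an explicit `outside` face.
#' @export
make_border_explicit <- function(m) {
  prov <- provisional_faces(m)
  if (length(prov) > 1L)
    stop("disconnected top level: more than one provisional complement", call. = FALSE)
  if (length(prov) == 1L) {
    fid <- prov
    m$faces[[as.character(fid)]]$provisional <- FALSE
    m$faces[[as.character(fid)]]$element_type <- "outside"
    sel <- darts(m)[!is.na(m$face_of[darts(m)]) & m$face_of[darts(m)] == fid]
    for (d in sel) m$props[[d]]$element_type <- "outside"
    validate_map(m)
    return(invisible(m))
  }
  has_outside <- any(vapply(m$faces, function(f)
    identical(f$element_type, "outside"), logical(1)))
  open_darts <- darts(m)[is.na(m$b2[darts(m)])]
  if (length(open_darts) == 0) {
    if (!has_outside && length(m$faces) == 0 && n_darts(m) > 0) {
      # raw closed kernel map without face records: nothing to do
    }
    validate_map(m)
    return(invisible(m))
  }
  tol <- m$tol
  border <- integer(0)
  for (d in open_darts) {
    h <- dart_head(m, d)
    b <- add_dart(m, h[1], h[2], list(element_type = "outside"))
    sew2(m, d, b)
    border <- c(border, b)
  }
  for (b in border) {
    h <- dart_head(m, b)  # origin of its partner
    ox <- m$x[border]; oy <- m$y[border]
    cand <- border[abs(ox - h[1]) <= tol & abs(oy - h[2]) <= tol]
    if (length(cand) != 1L)
      stop("ambiguous external border (node with several open darts)", call. = FALSE)
    m$b1[b] <- cand
  }
  fid <- new_face(m, anchor = border[1], element_type = "outside")
  m$face_of[border] <- fid
  validate_map(m)
  invisible(m)
}

#' Build a closed plot map from a plot specification
#'
#' Deterministic pipeline: one face per area in spec order, top-level faces
#' merged edge-to-edge, children embedded recursively as holes, and the
#' external border made explicit. Every dart carries the element type of its
#' incident face; the result validates closed.
#'
#' @param spec A [plot_spec()].
#' @return A closed `cmap2` map.
#' @export
build_plot <- function(spec) {
  stopifnot(inherits(spec, "plot_spec"))
  if (length(spec$areas) == 0) stop("empty plot spec", call. = FALSE)
  is_top <- vapply(spec$areas, function(a) is.na(a$parent), logical(1))
  if (!any(is_top)) stop("plot spec has no top-level area", call. = FALSE)
  area_ids <- vapply(spec$areas, function(a) a$id, character(1))
  m <- NULL
  face_of_area <- integer(0)
  for (a in spec$areas[is_top]) {
    frag <- withCallingHandlers(
      face_from_polygon(a$polygon, a$element_type,
                        c(a$attributes, list(area_id = a$id))),
      error = function(e) stop(sprintf("area '%s': %s", a$id, conditionMessage(e)),
                               call. = FALSE))
    fid <- attr(frag, "face_id")
    if (is.null(m)) {
      m <- frag
      face_of_area[a$id] <- fid
    } else {
      off <- m$next_face - 1L
      merge_maps(m, frag)
      face_of_area[a$id] <- fid + off
    }
  }
  make_border_explicit(m)
  # embed children in spec order; parents may themselves be embedded
  todo <- spec$areas[!is_top]
  guard <- 0L
  while (length(todo) > 0) {
    guard <- guard + 1L
    if (guard > length(spec$areas) + 1L)
      stop("unresolvable parent links in plot spec", call. = FALSE)
    rest <- list()
    for (a in todo) {
      if (!a$parent %in% names(face_of_area)) {
        if (!a$parent %in% area_ids)
          stop(sprintf("area '%s': unknown parent '%s'", a$id, a$parent), call. = FALSE)
        rest[[length(rest) + 1L]] <- a
        next
      }
      frag <- face_from_polygon(a$polygon, a$element_type,
                                c(a$attributes, list(area_id = a$id)))
      fid <- tryCatch(
        embed_hole(m, face_of_area[[a$parent]], frag),
        error = function(e) stop(sprintf("area '%s': %s", a$id, conditionMessage(e)),
                                 call. = FALSE))
      face_of_area[a$id] <- fid
    }
    todo <- rest
  }
  m$georef <- spec$georef
  rep <- validate_map(m)
  if (!rep$ok) stop("built plot map failed validation", call. = FALSE)
  invisible(m)
}

#' Find the face built from a given spec area id
#' @param m A map built by [build_plot()].
#' @param area_id Area id string from the plot spec.
#' @return Face id, or NA if absent.
#' @export
face_by_area <- function(m, area_id) {
  for (f in m$faces)
    if (identical(f$attributes$area_id, area_id)) return(f$id)
  NA_integer_
}
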
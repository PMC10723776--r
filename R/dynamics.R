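# Temporal evolution of a plot map. Attribute updates never touch the beta
# tables; structural edits (crown growth across a face border, element
# planting and thinning) are local surgery: only the darts of the affected
# faces are rebuilt, everything else keeps its ids, and every edit leaves the
# map closed and valid.

#' Update attributes without structural change
#'
#' Only attribute/property tables change; the beta tables are asserted
#' untouched.
#'
#' @param m A `cmap2` map (modified in place).
#' @param face Face id whose attributes to update (or NULL).
#' @param dart Dart id whose properties to update (or NULL).
#' @param updates Named list of scalar values.
#' @export
set_attributes <- function(m, face = NULL, dart = NULL, updates = list()) {
  h0 <- structural_hash(m)
  if (!is.null(face)) {
    rec <- get_face(m, face)
    rec$attributes[names(updates)] <- updates
    m$faces[[as.character(face)]] <- rec
  } else if (!is.null(dart)) {
    dart <- check_dart(m, dart)
    m$props[[dart]][names(updates)] <- updates
  } else stop("set_attributes: give a face or a dart target", call. = FALSE)
  stopifnot(identical(h0, structural_hash(m)))
  invisible(m)
}

#' Hash of the structural (beta) tables
#'
#' Attribute edits must leave this unchanged; structural edits change it.
#'
#' @param m A `cmap2` map.
#' @return A character scalar.
#' @export
structural_hash <- function(m) {
  ids <- darts(m)
  paste(ids, m$b1[ids], m$b2[ids], sep = ":", collapse = ";")
}

#' Plant a new embedded element
#'
#' Adds a face strictly inside a parent face via a hole (tree planting,
#' including scattered trees directly on a crop face).
#'
#' @param m A closed `cmap2` map (modified in place).
#' @param parent Parent face id.
#' @param polygon Element polygon (strictly inside the parent, clear of its
#'   holes).
#' @param element_type Element type of the new face.
#' @param attributes Named list of attributes.
#' @return The new face id.
#' @export
add_element <- function(m, parent, polygon, element_type, attributes = list()) {
  frag <- face_from_polygon(polygon, element_type, attributes)
  fid <- embed_hole(m, parent, frag)
  rep <- validate_map(m)
  if (!rep$ok) stop("add_element left the map inconsistent", call. = FALSE)
  fid
}

#' Remove an element from the map
#'
#' An embedded element (a face with a parent) is deleted together with its
#' hole cycle, restoring a hole-free region of the parent. A top-level face
#' is merged into a named neighbouring face: the shared-edge darts are
#' removed and the border cycles reconnected. Removing the outside face is
#' an error.
#'
#' @param m A closed `cmap2` map (modified in place).
#' @param face Face id to remove.
#' @param into For a top-level face, the adjacent face absorbing it.
#' @export
remove_element <- function(m, face, into = NULL) {
  rec <- get_face(m, face)
  if (identical(rec$element_type, "outside"))
    stop("cannot remove the outside face", call. = FALSE)
  if (!is.na(rec$parent)) {
    if (length(rec$holes))
      stop("remove embedded children before removing their parent", call. = FALSE)
    ids <- darts(m)
    fill <- ids[m$face_of[ids] %in% rec$id & is.na(m$hole_of[ids])]
    hole <- ids[m$hole_of[ids] %in% rec$id]
    for (d in c(hole, fill)) remove_dart(m, d)
    p <- as.character(rec$parent)
    keep <- vapply(m$faces[[p]]$holes, function(h) h$child != rec$id, logical(1))
    m$faces[[p]]$holes <- m$faces[[p]]$holes[keep]
    m$faces[[as.character(face)]] <- NULL
    rep <- validate_map(m)
    if (!rep$ok) stop("remove_element left the map inconsistent", call. = FALSE)
    return(invisible(m))
  }
  if (is.null(into))
    stop("removing a top-level face requires a neighbour face (into=)", call. = FALSE)
  irec <- get_face(m, into)
  ids <- darts(m)
  shared <- ids[m$face_of[ids] %in% face & is.na(m$hole_of[ids]) &
                  m$face_of[m$b2[ids]] %in% into]
  if (length(shared) == 0)
    stop("faces are not adjacent: nothing to merge along", call. = FALSE)
  for (e1 in shared) {
    if (!m$alive[e1]) next
    e2 <- m$b2[e1]
    p1 <- which(m$alive & !is.na(m$b1) & m$b1 == e1)
    p2 <- which(m$alive & !is.na(m$b1) & m$b1 == e2)
    n1 <- m$b1[e1]; n2 <- m$b1[e2]
    if (length(p1) == 1 && p1 != e2) m$b1[p1] <- n2
    if (length(p2) == 1 && p2 != e1) m$b1[p2] <- n1
    remove_dart(m, e1); remove_dart(m, e2)
  }
  ids <- darts(m)
  absorbed <- ids[m$face_of[ids] %in% face]
  m$face_of[absorbed] <- irec$id
  for (d in absorbed[is.na(m$hole_of[absorbed])])
    m$props[[d]]$element_type <- irec$element_type
  # transfer holes, fix the anchor if it was deleted
  m$faces[[as.character(into)]]$holes <-
    c(m$faces[[as.character(into)]]$holes, rec$holes)
  for (h in rec$holes)
    m$faces[[as.character(h$child)]]$parent <- irec$id
  if (!m$alive[irec$anchor]) {
    bd <- ids[m$face_of[ids] %in% into & is.na(m$hole_of[ids])]
    m$faces[[as.character(into)]]$anchor <- bd[1]
  }
  m$faces[[as.character(face)]] <- NULL
  rep <- validate_map(m)
  if (!rep$ok)
    stop("removing this face would leave an inconsistent map", call. = FALSE)
  invisible(m)
}

# import the live darts of fragment `b` into map `a`; returns the id map
import_darts <- function(a, b) {
  idmap <- integer(b$n_created)
  for (d in darts(b)) idmap[d] <- add_dart(a, b$x[d], b$y[d], b$props[[d]])
  for (d in darts(b)) {
    if (!is.na(b$b1[d])) a$b1[idmap[d]] <- idmap[b$b1[d]]
    if (!is.na(b$b2[d])) a$b2[idmap[d]] <- idmap[b$b2[d]]
  }
  idmap
}

#' Grow a tree crown, subdividing the ground faces it invades
#'
#' When the new crown stays inside the parent strip this is a pure resize of
#' the embedded tree face. When the crown projection crosses onto
#' neighbouring ground faces, the affected faces are locally re-tessellated:
#' the tree contributes one sub-face per ground face it covers (tagged with
#' its ground context and a common `group` attribute), the invaded crop
#' region becomes a `mixed` face carrying both tree and crop provenance, and
#' untouched faces keep their dart ids. Total interior area is conserved and
#' dual adjacencies can only be gained, never lost.
#'
#' Crowns are axis-aligned rectangles; each affected ground face must be
#' invaded across a single straight border run (otherwise
#' "non-conforming overlay").
#'
#' @param m A closed `cmap2` map (modified in place).
#' @param tree Face id of an embedded tree.
#' @param crown New crown polygon (axis-aligned rectangle containing the old
#'   crown), as a matrix or a bbox vector `c(xmin, xmax, ymin, ymax)`.
#' @param label Optional timestamp label stored on the new faces.
#' @return `m`, with attribute `new_faces` listing the created face ids.
#' @export
grow_crown <- function(m, tree, crown, label = NULL) {
  trec <- get_face(m, tree)
  if (is.na(trec$parent))
    stop("grow_crown targets an embedded tree face", call. = FALSE)
  tol <- m$tol
  if (is.matrix(crown) || is.data.frame(crown)) {
    cp <- dedup_poly(crown)
    bb <- poly_bbox(cp)
    if (abs(abs(signed_area(cp)) -
            (bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"])) > 1e-6)
      stop("crown must be an axis-aligned rectangle", call. = FALSE)
    crown <- bb
  } else {
    crown <- c(xmin = crown[[1]], xmax = crown[[2]],
               ymin = crown[[3]], ymax = crown[[4]])
  }
  oldbb <- poly_bbox(face_polygon(m, tree))
  if (crown["xmin"] > oldbb["xmin"] + tol || crown["xmax"] < oldbb["xmax"] - tol ||
      crown["ymin"] > oldbb["ymin"] + tol || crown["ymax"] < oldbb["ymax"] - tol)
    stop("new crown must contain the old crown", call. = FALSE)
  crown_poly <- rect_poly(crown["xmin"], crown["ymin"], crown["xmax"], crown["ymax"])
  parent <- trec$parent
  top <- faces(m, top_only = TRUE)
  interior <- top[vapply(top, function(f)
    !identical(face_element_type(m, f), "outside"), logical(1))]
  affected <- interior[vapply(interior, function(f)
    polys_overlap(crown_poly, face_polygon(m, f)), logical(1))]
  if (length(affected) == 0) stop("crown overlaps no ground face", call. = FALSE)
  ppoly <- face_polygon(m, parent)
  attrs <- trec$attributes
  if (!is.null(label)) attrs$grown_at <- label
  if (length(affected) == 1 && affected == parent &&
      poly_strictly_inside(crown_poly, ppoly)) {
    # pure resize inside the strip: no top-level change
    remove_element(m, tree)
    nid <- add_element(m, parent, crown_poly, "tree",
                       c(attrs, list(group = tree)))
    attr(m, "new_faces") <- nid
    return(invisible(m))
  }
  if (!(parent %in% affected))
    stop("crown no longer covers its parent strip", call. = FALSE)
  # ---- straddle case: local re-tessellation of the affected faces ----
  pieces_in <- list(); pieces_out <- list()
  total_in <- 0
  for (f in affected) {
    fpoly <- face_polygon(m, f)
    if (signed_area(fpoly) < 0)
      stop("non-conforming overlay (affected face is not interior)", call. = FALSE)
    R <- bbox_intersect(crown, poly_bbox(fpoly), tol)
    if (is.null(R)) stop("non-conforming overlay", call. = FALSE)
    rp <- rect_poly(R["xmin"], R["ymin"], R["xmax"], R["ymax"])
    if (any(points_strictly_inside(fpoly, rp)))
      stop("non-conforming overlay (face corner inside the crown)", call. = FALSE)
    for (h in face_holes(m, f)) {
      if (h == tree) next
      if (polys_overlap(face_polygon(m, h), rp))
        stop("non-conforming overlay (crown collides with an embedded element)",
             call. = FALSE)
    }
    out_poly <- tryCatch(splice_notch(fpoly, R, tol),
                         error = function(e)
                           stop("non-conforming overlay (crown not flush with one border run)",
                                call. = FALSE))
    pieces_in[[as.character(f)]] <- rp
    pieces_out[[as.character(f)]] <- out_poly
    total_in <- total_in + (R["xmax"] - R["xmin"]) * (R["ymax"] - R["ymin"])
  }
  crown_area <- (crown["xmax"] - crown["xmin"]) * (crown["ymax"] - crown["ymin"])
  if (abs(total_in - crown_area) > 1e-6 * crown_area)
    stop("crown escaping the plot outline", call. = FALSE)
  # drop the old tree (hole + filling), then snapshot the affected records
  remove_element(m, tree)
  frecs <- lapply(affected, function(f) get_face(m, f))
  names(frecs) <- affected
  # delete the boundary darts of the affected faces (holes stay)
  ids <- darts(m)
  for (f in affected) {
    bd <- ids[m$face_of[ids] %in% f & is.na(m$hole_of[ids]) & m$alive[ids]]
    for (d in bd) remove_dart(m, d)
  }
  # nodes on the seam that the new fragments must conform to
  ids <- darts(m)
  dangling <- ids[is.na(m$b2[ids])]
  dpts <- NULL
  for (d in dangling) dpts <- rbind(dpts, c(m$x[d], m$y[d]), dart_head(m, d))
  conform <- function(poly) insert_collinear_nodes(poly, dpts, tol)
  # assemble the replacement fragments in a scratch sub-map
  ord <- c(parent, setdiff(affected, parent))
  sub <- NULL
  sub_face_info <- list()   # fragment face id -> final face description
  add_frag <- function(sub, poly, et, at) {
    frag <- face_from_polygon(conform(poly), et, at)
    if (is.null(sub)) {
      list(sub = frag, fid = attr(frag, "face_id"))
    } else {
      off <- sub$next_face - 1L
      merge_maps(sub, frag)
      list(sub = sub, fid = attr(frag, "face_id") + off)
    }
  }
  for (f in ord) {
    fr <- frecs[[as.character(f)]]
    res <- add_frag(sub, pieces_out[[as.character(f)]], fr$element_type, fr$attributes)
    sub <- res$sub
    sub_face_info[[as.character(res$fid)]] <-
      list(final_id = f, holes = fr$holes, parent = fr$parent)
    if (f == parent) {
      res <- add_frag(sub, pieces_in[[as.character(f)]], "tree",
                      c(attrs, list(group = tree, context = fr$element_type)))
      sub <- res$sub
      sub_face_info[[as.character(res$fid)]] <- list(final_id = NA, holes = list())
    } else {
      res <- add_frag(sub, pieces_in[[as.character(f)]], "mixed",
                      list(group = tree, tree_id = tree, crop_id = f,
                           context = fr$element_type))
      sub <- res$sub
      sub_face_info[[as.character(res$fid)]] <- list(final_id = NA, holes = list())
    }
  }
  # import the sub-map; sew its complement seam onto the dangling kept darts
  idmap <- import_darts(m, sub)
  prov <- provisional_faces(sub)
  stopifnot(length(prov) == 1L)
  sids <- darts(sub)
  comp <- sids[sub$face_of[sids] %in% prov]
  for (c0 in comp) {
    c1 <- idmap[c0]
    # the kept dart plays the complement's own role (far side of the new
    # interior dart), so it runs in the same direction as the complement
    o <- c(m$x[c1], m$y[c1]); h <- dart_head(m, c1)
    k <- dangling[vapply(dangling, function(d)
      same_pt(c(m$x[d], m$y[d]), o, tol) && same_pt(dart_head(m, d), h, tol),
      logical(1))]
    if (length(k) != 1L)
      stop("non-conforming overlay (seam mismatch with neighbouring faces)",
           call. = FALSE)
    inner <- m$b2[c1]
    remove_dart(m, c1)
    sew2(m, inner, k)
  }
  # face records for the rebuilt region
  new_ids <- integer(0)
  for (sfid in names(sub_face_info)) {
    info <- sub_face_info[[sfid]]
    srec <- get_face(sub, as.integer(sfid))
    anchor <- idmap[srec$anchor]
    if (!is.na(info$final_id)) {
      fid <- info$final_id
      m$faces[[as.character(fid)]]$anchor <- anchor
      m$faces[[as.character(fid)]]$holes <- info$holes
    } else {
      fid <- new_face(m, anchor = anchor, element_type = srec$element_type,
                      attributes = srec$attributes, parent = NA_integer_)
      new_ids <- c(new_ids, fid)
    }
    cyc <- sids[sub$face_of[sids] %in% as.integer(sfid)]
    m$face_of[idmap[cyc]] <- fid
  }
  rep <- validate_map(m)
  if (!rep$ok) stop("grow_crown left the map inconsistent", call. = FALSE)
  attr(m, "new_faces") <- new_ids
  invisible(m)
}

# Canonical form & isomorphism ----------------------------------------------

# breadth-first relabelling of one beta-connected component from a given
# anchor, exploring beta1 before beta2; returns an encoding string
encode_from <- function(m, anchor, comp) {
  relab <- integer(0)
  relab[as.character(anchor)] <- 1L
  order_ids <- anchor
  queue <- anchor
  while (length(queue)) {
    d <- queue[1]; queue <- queue[-1]
    for (nb in c(m$b1[d], m$b2[d])) {
      if (is.na(nb) || !is.na(relab[as.character(nb)])) next
      relab[as.character(nb)] <- length(order_ids) + 1L
      order_ids <- c(order_ids, nb)
      queue <- c(queue, nb)
    }
  }
  if (length(order_ids) != length(comp)) return(NULL)  # not spanning (shouldn't happen)
  enc <- vapply(order_ids, function(d) {
    et <- m$props[[d]]$element_type
    sprintf("%s,%s,%s,%.9f,%.9f",
            relab[as.character(m$b1[d])], relab[as.character(m$b2[d])],
            if (is.null(et)) "" else et, m$x[d], m$y[d])
  }, character(1))
  paste(enc, collapse = "|")
}

#' Canonical form of a map
#'
#' Deterministic relabelling-invariant encoding: per beta-connected
#' component, breadth-first relabelling from every dart with the
#' lexicographically smallest (element_type, x, y) key, keeping the smallest
#' encoding; component encodings sorted and concatenated. Two maps have equal
#' canonical forms iff they are attributed-isomorphic up to dart renumbering.
#'
#' @param m A closed `cmap2` map.
#' @return A character scalar.
#' @export
canonical_form <- function(m) {
  ids <- darts(m)
  # beta-connected components
  comp_id <- integer(0)
  comps <- list()
  seen <- rep(FALSE, length(ids)); names(seen) <- ids
  for (d in ids) {
    if (seen[as.character(d)]) next
    comp <- integer(0); queue <- d
    seen[as.character(d)] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      for (nb in c(m$b1[cur], m$b2[cur])) {
        if (is.na(nb) || seen[as.character(nb)]) next
        seen[as.character(nb)] <- TRUE
        queue <- c(queue, nb)
      }
    }
    comps[[length(comps) + 1L]] <- comp
  }
  enc_all <- vapply(comps, function(comp) {
    key <- vapply(comp, function(d) {
      et <- m$props[[d]]$element_type
      sprintf("%s|%.9f|%.9f", if (is.null(et)) "" else et, m$x[d], m$y[d])
    }, character(1))
    anchors <- comp[key == min(key)]
    encs <- vapply(anchors, function(a) encode_from(m, a, comp), character(1))
    min(encs)
  }, character(1))
  paste(sort(enc_all), collapse = "||")
}

#' Attributed isomorphism of two maps
#'
#' TRUE when the maps are identical up to dart renumbering (same beta
#' structure, element types and coordinates).
#'
#' @param a,b Closed `cmap2` maps.
#' @export
map_isomorphic <- function(a, b) {
  if (n_darts(a) != n_darts(b)) return(FALSE)
  identical(canonical_form(a), canonical_form(b))
}

# Scenario events ------------------------------------------------------------

#' Read a JSON-lines event file
#'
#' One event per line: `{"op":"grow","tree":id,"crown":[[x,y],...]}`,
#' `{"op":"add","parent":id,"polygon":[[x,y],...],"element_type":...}`,
#' `{"op":"remove","face":id}` or
#' `{"op":"set","face":id,"updates":{...}}`.
#'
#' @param path Path to a JSON-lines file.
#' @return List of event records.
#' @export
read_events <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' Apply a list of events to a map
#'
#' @param m A closed `cmap2` map (modified in place).
#' @param events List from [read_events()].
#' @export
apply_events <- function(m, events) {
  for (ev in events) {
    op <- ev$op
    if (identical(op, "grow")) {
      grow_crown(m, ev$tree, as.matrix(ev$crown), label = ev$label)
    } else if (identical(op, "add")) {
      add_element(m, ev$parent, as.matrix(ev$polygon), ev$element_type,
                  as.list(ev$attributes))
    } else if (identical(op, "remove")) {
      remove_element(m, ev$face, into = ev$into)
    } else if (identical(op, "set")) {
      set_attributes(m, face = ev$face, updates = as.list(ev$updates))
    } else stop(sprintf("unknown event op: %s", op), call. = FALSE)
  }
  invisible(m)
}
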
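# Dual map derivation: faces become nodes, darts become oriented relations
# between elements. The dual shares the primal's dart set and beta2; its
# successor is the vertex rotation beta1_dual(d) = beta1(beta2(d)), so dual
# face orbits are the primal's node orbits and applying the construction
# twice recovers the primal's beta1 exactly. Duals are recomputed on demand
# (lazy views), so structural edits can never desynchronize the two
# representations.

#' Build the dual of a combinatorial map
#'
#' Works per hierarchy level: by default on the top level (top-level faces
#' and the outside face); pass a parent face id to build the dual of its
#' embedded level. The result is itself a valid closed `cmap2` whose dart
#' origins are placed at the centroid of the primal face each dart emanates
#' from, with metadata attributes `node_of` (dart id -> primal face id) and
#' `placement` (primal face id -> centroid).
#'
#' @param m A closed `cmap2` map.
#' @param parent NULL for the top level, or a parent face id.
#' @return A `cmap2` holding the dual, with attributes `node_of` and
#'   `placement`.
#' @export
build_dual <- function(m, parent = NULL) {
  ids <- if (length(m$faces)) level_darts(m, parent) else darts(m)
  if (length(ids) == 0) stop("build_dual: empty dart set", call. = FALSE)
  if (any(is.na(m$b1[ids])) || any(is.na(m$b2[ids])))
    stop("build_dual requires a closed map", call. = FALSE)
  if (!all(m$b2[ids] %in% ids))
    stop("build_dual: dart level is not beta2-closed", call. = FALSE)
  # dual node of a dart: its face when face records exist, else its beta1
  # orbit index (lets the construction apply to a dual again)
  if (length(m$faces)) {
    node_of <- m$face_of[ids]
    names(node_of) <- ids
    # darts on a hole cycle bound the parent face but at the embedded level
    # they stand for the parent (context) node; keep face_of semantics.
    placement <- list()
    for (f in unique(node_of)) {
      rec <- m$faces[[as.character(f)]]
      anchor_ids <- ids[node_of == f]
      placement[[as.character(f)]] <- poly_centroid(dart_origin(m, orbit_face(m, anchor_ids[1])))
    }
  } else {
    orbs <- face_orbits(m, ids)
    node_of <- integer(length(ids)); names(node_of) <- ids
    placement <- list()
    for (k in seq_along(orbs)) {
      node_of[as.character(orbs[[k]])] <- k
      placement[[as.character(k)]] <- poly_centroid(dart_origin(m, orbs[[k]]))
    }
  }
  dm <- cmap(tol = m$tol)
  dm$n_created <- max(ids)
  n <- max(ids)
  dm$b1 <- rep(NA_integer_, n); dm$b2 <- rep(NA_integer_, n)
  dm$x <- rep(NA_real_, n); dm$y <- rep(NA_real_, n)
  dm$alive <- rep(FALSE, n)
  dm$props <- vector("list", n)
  dm$face_of <- rep(NA_integer_, n); dm$hole_of <- rep(NA_integer_, n)
  for (d in ids) {
    dm$alive[d] <- TRUE
    dm$b2[d] <- m$b2[d]
    dm$b1[d] <- m$b1[m$b2[d]]
    ctr <- placement[[as.character(node_of[as.character(d)])]]
    dm$x[d] <- ctr[1]; dm$y[d] <- ctr[2]
    dm$props[[d]] <- list(node = unname(node_of[as.character(d)]))
  }
  dm$closed <- TRUE
  labels <- vapply(unique(node_of), function(f) {
    if (length(m$faces)) {
      et <- m$faces[[as.character(f)]]$element_type
      if (is.na(et)) as.character(f) else et
    } else as.character(f)
  }, character(1))
  names(labels) <- unique(node_of)
  attr(dm, "node_of") <- node_of
  attr(dm, "node_label") <- labels
  attr(dm, "placement") <- placement
  attr(dm, "dual_of_level") <- if (is.null(parent)) NA_integer_ else parent
  dm
}

#' Interfaces between faces
#'
#' For every unordered pair of faces sharing at least one edge, the darts
#' realizing the interface oriented from the first face to the second (the
#' outside face included). The listing is symmetric: the darts of (B, A) are
#' the beta2 images of those of (A, B).
#'
#' @param m A closed `cmap2` map with face records.
#' @param parent NULL for the top level, or a parent face id (interfaces of
#'   its embedded level).
#' @return A list of records `list(face_a, face_b, darts)`, ordered by
#'   (face_a, face_b) with `face_a < face_b`.
#' @export
interfaces <- function(m, parent = NULL) {
  ids <- level_darts(m, parent)
  fa <- m$face_of[ids]
  fb <- m$face_of[m$b2[ids]]
  keep <- fa < fb
  key <- paste(fa[keep], fb[keep])
  out <- list()
  for (k in sort(unique(key))) {
    sel <- ids[keep][key == k]
    out[[length(out) + 1L]] <- list(face_a = fa[keep][key == k][1],
                                    face_b = fb[keep][key == k][1],
                                    darts = sort(sel))
  }
  out
}

#' Are two faces adjacent (share at least one edge)?
#' @param m A closed `cmap2` map.
#' @param f1,f2 Face ids.
#' @param parent Hierarchy level (see [interfaces()]).
#' @export
faces_adjacent <- function(m, f1, f2, parent = NULL) {
  any(vapply(interfaces(m, parent), function(it)
    (it$face_a == f1 && it$face_b == f2) || (it$face_a == f2 && it$face_b == f1),
    logical(1)))
}
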
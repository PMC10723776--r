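# The 2D combinatorial-map kernel: darts, the beta1 permutation and the beta2
# involution, orbits, validation and copying. A map is an environment-backed
# S3 object ("cmap2"), so the surgical operations of the builder and the
# dynamics layer run with reference semantics; copy_map() gives a deep copy.
#
# Storage: dart ids are consecutive positive integers in creation order and
# are never reused after deletion. The beta tables are id-indexed integer
# vectors (NA = unset), which keeps every lookup O(1) and serialization
# trivial. Face bookkeeping (used by the builder layers) lives alongside:
# each dart belongs to the face lying on its left; darts forming the inner
# boundary of a hole additionally record which embedded face fills the hole.

#' Create an empty 2D combinatorial map
#'
#' A combinatorial map is a set of oriented half-edges (darts) together with
#' a permutation `beta1` (next dart along the border of the same face) and an
#' involution `beta2` (the oppositely oriented partner dart across the shared
#' edge). Faces, edges and nodes are all recovered as orbits of these two
#' operators.
#'
#' @param tol Coordinate tolerance in metres used for node-identity tests.
#' @return An object of class `cmap2`.
#' @seealso [add_dart()], [link1()], [sew2()], [validate_map()]
#' @export
cmap <- function(tol = 1e-9) {
  m <- new.env(parent = emptyenv())
  m$b1 <- integer(0)        # id -> beta1 successor (NA unset)
  m$b2 <- integer(0)        # id -> beta2 partner   (NA unset)
  m$x <- numeric(0)
  m$y <- numeric(0)
  m$alive <- logical(0)
  m$props <- list()         # id -> named list of scalar properties
  m$face_of <- integer(0)   # id -> face id (NA until faces assigned)
  m$hole_of <- integer(0)   # id -> embedded face filling the hole this dart bounds
  m$n_created <- 0L
  m$faces <- list()         # face id (as character) -> face record
  m$next_face <- 1L
  m$closed <- FALSE
  m$tol <- tol
  m$georef <- NULL
  class(m) <- "cmap2"
  m
}

#' @export
print.cmap2 <- function(x, ...) {
  ids <- darts(x)
  cat(sprintf("<cmap2: %d darts, %d faces%s>\n", length(ids),
              length(x$faces), if (isTRUE(x$closed)) ", closed" else ""))
  invisible(x)
}

#' Dart ids currently present in a map
#' @param m A `cmap2` map.
#' @return Sorted integer vector of live dart ids.
#' @export
darts <- function(m) which(m$alive)

#' Number of darts in a map
#' @param m A `cmap2` map.
#' @export
n_darts <- function(m) sum(m$alive)

check_dart <- function(m, d, what = "dart") {
  if (length(d) != 1L || is.na(d) || d < 1L || d > m$n_created || !m$alive[d])
    stop(sprintf("unknown %s id: %s", what, paste(d, collapse = ",")), call. = FALSE)
  invisible(as.integer(d))
}

#' Add a dart to a map
#'
#' The new dart gets a fresh id (consecutive, never reused), carries its
#' origin coordinates and an arbitrary property bag, and starts with both
#' beta links unset. The map is marked not closed.
#'
#' @param m A `cmap2` map (modified in place).
#' @param x,y Origin coordinates of the dart in plot-local metres.
#' @param properties Named list of scalar properties.
#' @return The id of the new dart.
#' @export
add_dart <- function(m, x, y, properties = list()) {
  id <- m$n_created + 1L
  m$n_created <- id
  m$b1[id] <- NA_integer_; m$b2[id] <- NA_integer_
  m$x[id] <- as.numeric(x); m$y[id] <- as.numeric(y)
  m$alive[id] <- TRUE
  m$props[[id]] <- properties
  m$face_of[id] <- NA_integer_
  m$hole_of[id] <- NA_integer_
  m$closed <- FALSE
  id
}

#' Remove a dart from a map
#'
#' Any dart whose beta1 or beta2 pointed at the removed dart has that link
#' unset; the freed id is never reassigned.
#'
#' @param m A `cmap2` map (modified in place).
#' @param d Dart id to remove.
#' @export
remove_dart <- function(m, d) {
  d <- check_dart(m, d)
  preds <- which(!is.na(m$b1) & m$b1 == d & m$alive)
  if (length(preds)) m$b1[preds] <- NA_integer_
  partner <- m$b2[d]
  if (!is.na(partner) && m$alive[partner]) m$b2[partner] <- NA_integer_
  others <- which(!is.na(m$b2) & m$b2 == d & m$alive)
  if (length(others)) m$b2[others] <- NA_integer_
  m$alive[d] <- FALSE
  m$b1[d] <- NA_integer_; m$b2[d] <- NA_integer_
  m$props[d] <- list(NULL)
  m$face_of[d] <- NA_integer_; m$hole_of[d] <- NA_integer_
  m$closed <- FALSE
  invisible(m)
}

#' Set the beta1 successor of a dart
#'
#' `beta1` is the permutation that walks the border of a face: `link1(m, d, e)`
#' declares `e` the next dart after `d` along their common face. Relinking
#' overwrites the previous successor.
#'
#' @param m A `cmap2` map (modified in place).
#' @param d,e Dart ids.
#' @export
link1 <- function(m, d, e) {
  d <- check_dart(m, d); e <- check_dart(m, e)
  m$b1[d] <- e
  invisible(m)
}

#' Sew two darts by the beta2 involution
#'
#' Declares `d` and `e` oppositely oriented halves of the same edge:
#' `beta2(d) = e` and `beta2(e) = d`. Sewing a dart to itself is an error
#' (beta2 must be fixed-point free on a closed map). Re-sewing an already
#' sewn pair is a no-op; sewing a dart that is sewn elsewhere is an error
#' unless `force = TRUE`, which first unsews both.
#'
#' @param m A `cmap2` map (modified in place).
#' @param d,e Dart ids.
#' @param force Unsew existing partners first.
#' @export
sew2 <- function(m, d, e, force = FALSE) {
  d <- check_dart(m, d); e <- check_dart(m, e)
  if (d == e) stop("cannot sew a dart to itself: beta2 must be fixed-point free",
                   call. = FALSE)
  if (identical(m$b2[d], e) && identical(m$b2[e], d)) return(invisible(m))
  if (!force && (!is.na(m$b2[d]) || !is.na(m$b2[e])))
    stop(sprintf("dart %d or %d is already beta2-sewn (use force = TRUE)", d, e),
         call. = FALSE)
  for (z in c(d, e)) {
    old <- m$b2[z]
    if (!is.na(old) && m$alive[old]) m$b2[old] <- NA_integer_
  }
  m$b2[d] <- e; m$b2[e] <- d
  invisible(m)
}

#' Unset the beta2 link of a dart (and of its partner)
#' @param m A `cmap2` map (modified in place).
#' @param d Dart id.
#' @export
unsew2 <- function(m, d) {
  d <- check_dart(m, d)
  old <- m$b2[d]
  if (!is.na(old) && m$alive[old]) m$b2[old] <- NA_integer_
  m$b2[d] <- NA_integer_
  invisible(m)
}

#' Beta operator accessors
#'
#' @param m A `cmap2` map.
#' @param d Dart id (vectorized).
#' @return Dart id(s), NA where unset.
#' @export
beta1 <- function(m, d) m$b1[d]

#' @rdname beta1
#' @export
beta2 <- function(m, d) m$b2[d]

#' Origin coordinates of darts
#' @param m A `cmap2` map.
#' @param d Dart ids.
#' @return Two-column matrix (x, y).
#' @export
dart_origin <- function(m, d) cbind(x = m$x[d], y = m$y[d])

#' Face orbit of a dart
#'
#' Repeatedly applies beta1 from `d` until `d` recurs, yielding the ordered
#' cyclic border of the face issued from `d`.
#'
#' @param m A `cmap2` map.
#' @param d Start dart id.
#' @return Integer vector of dart ids starting at `d`.
#' @export
orbit_face <- function(m, d) {
  d <- check_dart(m, d)
  out <- integer(0)
  cur <- d
  limit <- n_darts(m)
  repeat {
    out <- c(out, cur)
    cur <- m$b1[cur]
    if (is.na(cur) || length(out) > limit) stop("face not closed", call. = FALSE)
    if (cur == d) break
  }
  out
}

#' Node orbit of a dart
#'
#' Collects every dart incident to the head node of `d` by alternately
#' applying beta1 then beta2, starting with beta1. On a closed map the walk
#' stops when the start dart recurs; on an open map it stops at the first
#' unset link and returns the truncated chain.
#'
#' @param m A `cmap2` map.
#' @param d Start dart id.
#' @return Integer vector of dart ids, starting at `d`.
#' @export
orbit_node <- function(m, d) {
  d <- check_dart(m, d)
  seq_out <- d
  cur <- d
  limit <- 2L * n_darts(m) + 2L
  repeat {
    nxt <- m$b1[cur]
    if (is.na(nxt)) break
    if (!(nxt %in% seq_out)) seq_out <- c(seq_out, nxt)
    cur <- m$b2[nxt]
    if (is.na(cur)) break
    if (cur == d) break
    if (!(cur %in% seq_out)) seq_out <- c(seq_out, cur)
    if (length(seq_out) > limit) stop("orbit_node did not terminate", call. = FALSE)
  }
  seq_out
}

#' Vertex orbit of a dart
#'
#' All darts sharing the origin node of `d`, obtained by iterating the vertex
#' rotation (apply beta2, then beta1). Unlike [orbit_node()], these orbits
#' partition the dart set, so counting them counts the nodes of the map.
#' Requires a closed map.
#'
#' @param m A `cmap2` map.
#' @param d Start dart id.
#' @return Integer vector of dart ids starting at `d`.
#' @export
orbit_vertex <- function(m, d) {
  d <- check_dart(m, d)
  out <- integer(0)
  cur <- d
  limit <- n_darts(m)
  repeat {
    out <- c(out, cur)
    nxt <- m$b2[cur]
    if (is.na(nxt)) stop("orbit_vertex requires a closed map (unset beta2)", call. = FALSE)
    cur <- m$b1[nxt]
    if (is.na(cur)) stop("orbit_vertex requires a closed map (unset beta1)", call. = FALSE)
    if (cur == d) break
    if (length(out) > limit) stop("orbit_vertex did not terminate", call. = FALSE)
  }
  out
}

#' Apply a custom orbit operator sequence
#'
#' Applies a composition of beta operators to a dart. Following mathematical
#' composition notation, the sequence is applied right to left: with
#' `ops = c("beta1", "beta2")` the result is `beta1(beta2(d))`.
#'
#' @param m A `cmap2` map.
#' @param d Start dart id.
#' @param ops Character vector over `"beta1"`, `"beta2"`.
#' @return The resulting dart id.
#' @export
orbit_custom <- function(m, d, ops) {
  d <- check_dart(m, d)
  if (length(ops) == 0) return(d)
  ops <- match.arg(ops, c("beta1", "beta2"), several.ok = TRUE)
  cur <- d
  for (k in rev(seq_along(ops))) {
    nxt <- if (ops[k] == "beta1") m$b1[cur] else m$b2[cur]
    if (is.na(nxt))
      stop(sprintf("orbit_custom: %s is unset at dart %d (step %d of %d)",
                   ops[k], cur, length(ops) - k + 1L, length(ops)), call. = FALSE)
    cur <- nxt
  }
  cur
}

# Partition live darts (or a subset) into orbits of a successor function.
orbit_partition <- function(ids, succ) {
  seen <- rep(FALSE, length(ids))
  names(seen) <- ids
  orbits <- list()
  for (d in ids) {
    if (seen[as.character(d)]) next
    orb <- integer(0)
    cur <- d
    repeat {
      orb <- c(orb, cur)
      seen[as.character(cur)] <- TRUE
      cur <- succ(cur)
      if (is.na(cur) || cur == d) break
      if (seen[as.character(cur)]) break
    }
    orbits[[length(orbits) + 1L]] <- orb
  }
  orbits
}

#' All face orbits of a map
#' @param m A `cmap2` map.
#' @param ids Dart subset (default all live darts).
#' @return List of integer vectors, one per face orbit.
#' @export
face_orbits <- function(m, ids = darts(m)) orbit_partition(ids, function(d) m$b1[d])

#' All vertex orbits of a map
#' @param m A `cmap2` map.
#' @param ids Dart subset (default all live darts).
#' @return List of integer vectors, one per node of the map.
#' @export
vertex_orbits <- function(m, ids = darts(m)) {
  orbit_partition(ids, function(d) {
    p <- m$b2[d]
    if (is.na(p)) NA_integer_ else m$b1[p]
  })
}

#' Structural counts of a closed map
#'
#' @param m A `cmap2` map.
#' @param ids Dart subset defining a closed sub-map (default all darts).
#' @return Named vector with `V` (vertex orbits), `E` (beta2 edge pairs),
#'   `F` (face orbits) and `euler` = V - E + F.
#' @export
map_counts <- function(m, ids = darts(m)) {
  V <- length(vertex_orbits(m, ids))
  E <- length(ids) / 2
  F_ <- length(face_orbits(m, ids))
  c(V = V, E = E, F = F_, euler = V - E + F_)
}

#' Validate a combinatorial map
#'
#' Checks the structural axioms: beta1 totality and bijectivity, beta2
#' totality, involution and fixed-point freeness, and geometric coherence
#' (the beta1 successor and the beta2 partner of a dart both start at its
#' head node). All problems are reported, none raised. The map's `closed`
#' flag is set accordingly.
#'
#' @param m A `cmap2` map.
#' @param tol Coordinate tolerance (default the map's).
#' @return An object of class `agromap_validation`: list with `ok` and
#'   `violations` (list of `rule` / `darts` records).
#' @export
validate_map <- function(m, tol = m$tol) {
  ids <- darts(m)
  viol <- list()
  bad <- function(rule, ds) {
    if (length(ds)) viol[[length(viol) + 1L]] <<- list(rule = rule, darts = sort(as.integer(ds)))
  }
  b1 <- m$b1[ids]; b2 <- m$b2[ids]
  bad("beta1-totality", ids[is.na(b1)])
  set1 <- ids[!is.na(b1)]
  tgt <- m$b1[set1]
  dangling <- set1[!(tgt %in% ids)]
  dup <- set1[tgt %in% tgt[duplicated(tgt)]]
  bad("beta1-bijectivity", union(dangling, dup))
  bad("beta2-totality", ids[is.na(b2)])
  set2 <- ids[!is.na(b2)]
  p <- m$b2[set2]
  badinv <- set2[!(p %in% ids) | is.na(m$b2[p]) | m$b2[p] != set2]
  bad("beta2-involution", badinv)
  bad("beta2-fixedpoint", set2[p == set2])
  both <- ids[!is.na(b1) & !is.na(b2)]
  if (length(both)) {
    s1 <- m$b1[both]; s2 <- m$b2[both]
    okref <- (s1 %in% ids) & (s2 %in% ids)
    both <- both[okref]; s1 <- s1[okref]; s2 <- s2[okref]
    dx <- abs(m$x[s1] - m$x[s2]); dy <- abs(m$y[s1] - m$y[s2])
    bad("geometric-coherence", both[dx > tol | dy > tol])
  }
  ok <- length(viol) == 0
  m$closed <- ok && length(ids) > 0
  structure(list(ok = ok, violations = viol), class = "agromap_validation")
}

#' @export
print.agromap_validation <- function(x, ...) {
  if (x$ok) cat("map is valid and closed\n")
  else for (v in x$violations)
    cat(sprintf("%s: darts %s\n", v$rule, paste(v$darts, collapse = ", ")))
  invisible(x)
}

#' Is a map closed?
#'
#' A map is closed when the external border is explicit and both beta
#' operators are total, i.e. [validate_map()] reports no violations.
#'
#' @param m A `cmap2` map.
#' @export
is_closed <- function(m) validate_map(m)$ok && n_darts(m) > 0

#' Deep copy of a map
#'
#' Structurally identical copy with the same dart ids; mutating the copy
#' never affects the original.
#'
#' @param m A `cmap2` map.
#' @return A new `cmap2`.
#' @export
copy_map <- function(m) {
  out <- cmap(tol = m$tol)
  for (f in c("b1", "b2", "x", "y", "alive", "props", "face_of", "hole_of",
              "n_created", "faces", "next_face", "closed", "georef"))
    assign(f, get(f, envir = m), envir = out)
  out
}

# Face records --------------------------------------------------------------

new_face <- function(m, anchor, element_type, attributes = list(),
                     parent = NA_integer_, provisional = FALSE, id = NULL) {
  if (is.null(id)) {
    id <- m$next_face
    m$next_face <- m$next_face + 1L
  } else {
    id <- as.integer(id)
    m$next_face <- max(m$next_face, id + 1L)
  }
  m$faces[[as.character(id)]] <- list(
    id = id, anchor = as.integer(anchor), element_type = element_type,
    attributes = attributes, holes = list(), parent = as.integer(parent),
    provisional = isTRUE(provisional))
  id
}

get_face <- function(m, f) {
  rec <- m$faces[[as.character(f)]]
  if (is.null(rec)) stop(sprintf("unknown face id: %s", f), call. = FALSE)
  rec
}

#' Face ids of a map
#' @param m A `cmap2` map.
#' @param top_only Only faces without a parent.
#' @export
faces <- function(m, top_only = FALSE) {
  ids <- vapply(m$faces, function(f) f$id, integer(1))
  if (top_only) ids <- ids[vapply(m$faces, function(f) is.na(f$parent), logical(1))]
  unname(sort(ids))
}

#' Face lookup helpers
#'
#' `face_element_type()` returns the element type of a face; `face_of_dart()`
#' the face lying on the left of a dart; `face_polygon()` the boundary
#' polygon read off the face's beta1 cycle; `face_holes()` the ids of the
#' faces embedded in its holes; `face_parent()` the parent face id (NA for a
#' top-level face).
#'
#' @param m A `cmap2` map.
#' @param f Face id.
#' @param d Dart id.
#' @export
face_element_type <- function(m, f) get_face(m, f)$element_type

#' @rdname face_element_type
#' @export
face_of_dart <- function(m, d) m$face_of[check_dart(m, d)]

#' @rdname face_element_type
#' @export
face_polygon <- function(m, f) {
  rec <- get_face(m, f)
  dart_origin(m, orbit_face(m, rec$anchor))
}

#' @rdname face_element_type
#' @export
face_holes <- function(m, f) {
  rec <- get_face(m, f)
  vapply(rec$holes, function(h) h$child, integer(1))
}

#' @rdname face_element_type
#' @export
face_parent <- function(m, f) get_face(m, f)$parent

#' Face attributes
#' @param m A `cmap2` map.
#' @param f Face id.
#' @export
face_attributes <- function(m, f) get_face(m, f)$attributes

#' Darts of one hierarchy level
#'
#' For `parent = NULL`: the boundary-cycle darts of every top-level face
#' (including the outside face), excluding hole cycles. For a face id: the
#' darts of that face's hole cycles together with the boundary darts of the
#' faces embedded in it. Each such subset is itself a closed sub-map.
#'
#' @param m A `cmap2` map.
#' @param parent NULL for the top level, or a face id.
#' @return Integer vector of dart ids.
#' @export
level_darts <- function(m, parent = NULL) {
  ids <- darts(m)
  if (is.null(parent)) {
    top <- faces(m, top_only = TRUE)
    ids[m$face_of[ids] %in% top & is.na(m$hole_of[ids])]
  } else {
    rec <- get_face(m, parent)
    kids <- face_holes(m, parent)
    ids[(m$face_of[ids] %in% parent & !is.na(m$hole_of[ids])) |
          (m$face_of[ids] %in% kids & is.na(m$hole_of[ids]))]
  }
}

#' Total interior area of a plot map
#'
#' Sum of the boundary areas of the top-level faces other than the outside
#' face (embedded elements lie inside their parents and are not added twice).
#'
#' @param m A closed `cmap2` map with face records.
#' @export
map_area <- function(m) {
  top <- faces(m, top_only = TRUE)
  tot <- 0
  for (f in top) {
    rec <- get_face(m, f)
    if (identical(rec$element_type, "outside") || rec$provisional) next
    tot <- tot + signed_area(face_polygon(m, f))
  }
  tot
}
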
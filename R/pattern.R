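# Exact matching of a small attributed map fragment (a structural /
# ecosystem-service pattern) inside a plot map.
#
# The matched domain is the set of boundary darts of the pattern's
# role-bearing faces: the pattern's own explicit border (its outside face)
# is a closure artifact, not a constraint, so beta2 preservation is required
# only where both endpoints lie in the domain. The dart mapping must be
# injective and preserve beta1 everywhere in the domain, which forces each
# pattern face onto a target face with a border cycle of the same length.
# Matches are deduplicated by the sorted set of matched target face ids
# (canonical key), so symmetric re-embeddings of the same face set count
# once.

#' Define a map pattern
#'
#' @param fragment A closed `cmap2` (typically built with [build_plot()] from
#'   a small spec).
#' @param roles Named character vector mapping fragment face ids (as names)
#'   to role labels. Only role-bearing faces are matched; leave the
#'   fragment's outside face out.
#' @param predicates List of constraints built with [pred_attr()],
#'   [pred_adjacent()], [pred_between()] or [pred_metric()].
#' @return An object of class `agromap_pattern`.
#' @export
pattern <- function(fragment, roles, predicates = list()) {
  stopifnot(inherits(fragment, "cmap2"))
  if (!validate_map(fragment)$ok) stop("pattern fragment must be closed", call. = FALSE)
  fids <- suppressWarnings(as.integer(names(roles)))
  if (anyNA(fids)) stop("role names must be fragment face ids", call. = FALSE)
  for (pr in predicates) {
    used <- unlist(pr[c("role", "a", "b", "c")], use.names = FALSE)
    if (!all(used %in% roles))
      stop("malformed predicate: unknown role", call. = FALSE)
  }
  structure(list(fragment = fragment,
                 roles = stats::setNames(as.character(roles), fids),
                 predicates = predicates),
            class = "agromap_pattern")
}

#' Pattern predicates
#'
#' `pred_attr()` requires an attribute of the matched face to equal a value.
#' `pred_adjacent()` requires two roles to share at least one edge.
#' `pred_between()` requires role `a` to share an edge with both `b` and `c`
#' while `b` and `c` share none ("crop must lay between two tree lines").
#' `pred_metric()` compares a face metric (see [eval_metric()]) with a value;
#' `op = "multiple_of"` accepts widths within `tol * value` of an integer
#' multiple ("alley width must be a multiple of the machine width").
#'
#' @param role,a,b,c Role labels.
#' @param key Attribute name.
#' @param value Comparison value.
#' @param metric One of `"width"`, `"height"`, `"area"`.
#' @param op One of `"=="`, `"<="`, `">="`, `"multiple_of"`.
#' @param tol Relative tolerance for `"multiple_of"` (default 0.01) or
#'   absolute tolerance for `"=="`.
#' @export
pred_attr <- function(role, key, value)
  list(type = "attr", role = role, key = key, value = value)

#' @rdname pred_attr
#' @export
pred_adjacent <- function(a, b) list(type = "adjacent", a = a, b = b)

#' @rdname pred_attr
#' @export
pred_between <- function(a, b, c) list(type = "between", a = a, b = b, c = c)

#' @rdname pred_attr
#' @export
pred_metric <- function(role, metric, op, value, tol = 0.01)
  list(type = "metric", role = role, metric = metric, op = op,
       value = value, tol = tol)

#' Evaluate a face metric
#'
#' `width` and `height` come from the axis-aligned bounding box of the
#' boundary cycle, `area` is the shoelace area minus the areas of the face's
#' holes, `centroid_x` / `centroid_y` the area-weighted boundary centroid.
#' All metres / square metres.
#'
#' @param m A closed `cmap2` map.
#' @param f Face id.
#' @param metric Metric name.
#' @return Numeric scalar.
#' @export
eval_metric <- function(m, f, metric) {
  poly <- face_polygon(m, f)
  bb <- poly_bbox(poly)
  switch(metric,
         width = unname(bb["xmax"] - bb["xmin"]),
         height = unname(bb["ymax"] - bb["ymin"]),
         area = {
           a <- abs(signed_area(poly))
           for (h in face_holes(m, f)) a <- a - abs(signed_area(face_polygon(m, h)))
           a
         },
         centroid_x = poly_centroid(poly)[1],
         centroid_y = poly_centroid(poly)[2],
         stop(sprintf("unknown metric: %s", metric), call. = FALSE))
}

check_predicates <- function(target, face_map, predicates, parent = NULL) {
  for (pr in predicates) {
    ok <- switch(pr$type,
      attr = {
        v <- face_attributes(target, face_map[[pr$role]])[[pr$key]]
        !is.null(v) && isTRUE(all.equal(v, pr$value))
      },
      adjacent = faces_adjacent(target, face_map[[pr$a]], face_map[[pr$b]], parent),
      between = {
        faces_adjacent(target, face_map[[pr$a]], face_map[[pr$b]], parent) &&
          faces_adjacent(target, face_map[[pr$a]], face_map[[pr$c]], parent) &&
          !faces_adjacent(target, face_map[[pr$b]], face_map[[pr$c]], parent)
      },
      metric = {
        v <- eval_metric(target, face_map[[pr$role]], pr$metric)
        switch(pr$op,
               "==" = abs(v - pr$value) <= pr$tol,
               "<=" = v <= pr$value + 1e-9,
               ">=" = v >= pr$value - 1e-9,
               multiple_of = abs(v - pr$value * round(v / pr$value)) <=
                 pr$tol * pr$value,
               stop(sprintf("unknown metric comparator: %s", pr$op), call. = FALSE))
      },
      stop(sprintf("malformed predicate type: %s", pr$type), call. = FALSE))
    if (!ok) return(FALSE)
  }
  TRUE
}

pattern_domain <- function(pat) {
  frag <- pat$fragment
  fids <- as.integer(names(pat$roles))
  ids <- darts(frag)
  ids[frag$face_of[ids] %in% fids & is.na(frag$hole_of[ids])]
}

#' Find all matches of a pattern in a target map
#'
#' Anchor-propagation search at the top hierarchy level: starting from every
#' compatible target dart, the injective dart mapping is extended in
#' lockstep along beta1 and (within the pattern domain) beta2; completed
#' mappings that satisfy all predicates are reported, deduplicated by
#' matched face set, and ordered deterministically.
#'
#' @param target A closed `cmap2` map.
#' @param pat An [pattern()] object.
#' @param anchor Optional pattern dart to anchor the search at (defaults to a
#'   dart of the rarest element type; the result does not depend on this).
#' @return List of matches, each `list(dart_map, face_map, canonical_key)`.
#' @export
find_matches <- function(target, pat, anchor = NULL) {
  stopifnot(inherits(pat, "agromap_pattern"))
  if (n_darts(target) == 0) return(list())
  dom <- pattern_domain(pat)
  frag <- pat$fragment
  tids <- level_darts(target)
  if (length(dom) > length(tids)) return(list())
  t_et <- vapply(tids, function(d) {
    et <- target$props[[d]]$element_type
    if (is.null(et)) NA_character_ else et
  }, character(1))
  p_et <- vapply(dom, function(d) {
    et <- frag$props[[d]]$element_type
    if (is.null(et)) NA_character_ else et
  }, character(1))
  if (is.null(anchor)) {
    counts <- table(t_et)
    freq <- vapply(p_et, function(e)
      if (e %in% names(counts)) counts[[e]] else 0L, numeric(1))
    if (any(freq == 0)) return(list())
    anchor <- dom[which.min(freq)]
  }
  in_dom <- rep(FALSE, frag$n_created); in_dom[dom] <- TRUE
  in_tgt <- rep(FALSE, target$n_created); in_tgt[tids] <- TRUE
  et_of_t <- rep(NA_character_, target$n_created); et_of_t[tids] <- t_et
  et_of_p <- rep(NA_character_, frag$n_created); et_of_p[dom] <- p_et
  # anchor first, then the rest of the domain in id order
  dom_order <- c(anchor, setdiff(dom, anchor))
  # lockstep propagation of one (pattern dart, target dart) seed
  propagate <- function(fwd, bwd, p0, t0) {
    queue <- list(c(p0, t0))
    while (length(queue)) {
      pr <- queue[[1]]; queue <- queue[-1]
      p <- pr[1]; t <- pr[2]
      if (fwd[p] != 0) { if (fwd[p] != t) return(NULL); next }
      if (bwd[t] != 0) return(NULL)
      if (!in_tgt[t] || !identical(et_of_p[p], et_of_t[t])) return(NULL)
      fwd[p] <- t; bwd[t] <- p
      queue[[length(queue) + 1L]] <- c(frag$b1[p], target$b1[t])
      p2 <- frag$b2[p]
      if (in_dom[p2]) queue[[length(queue) + 1L]] <- c(p2, target$b2[t])
    }
    list(fwd = fwd, bwd = bwd)
  }
  complete <- list()
  search <- function(fwd, bwd) {
    un <- dom_order[fwd[dom_order] == 0]
    if (length(un) == 0) {
      complete[[length(complete) + 1L]] <<- fwd
      return(invisible(NULL))
    }
    p0 <- un[1]
    for (t0 in tids[et_of_t[tids] == et_of_p[p0] & bwd[tids] == 0]) {
      st <- propagate(fwd, bwd, p0, t0)
      if (!is.null(st)) search(st$fwd, st$bwd)
    }
    invisible(NULL)
  }
  search(integer(frag$n_created), integer(target$n_created))
  matches <- list()
  seen_keys <- character(0)
  for (fwd in complete) {
    face_map <- list()
    consistent <- TRUE
    for (fid in names(pat$roles)) {
      fdarts <- dom[frag$face_of[dom] == as.integer(fid)]
      tfaces <- unique(target$face_of[fwd[fdarts]])
      if (length(tfaces) != 1L) { consistent <- FALSE; break }
      face_map[[pat$roles[[fid]]]] <- tfaces
    }
    if (!consistent) next
    if (anyDuplicated(unlist(face_map))) next
    if (!check_predicates(target, face_map, pat$predicates)) next
    key <- paste(sort(unlist(face_map)), collapse = ",")
    if (key %in% seen_keys) next
    seen_keys <- c(seen_keys, key)
    dm <- fwd[dom]; names(dm) <- dom
    matches[[length(matches) + 1L]] <-
      list(dart_map = dm, face_map = face_map, canonical_key = key)
  }
  matches[order(vapply(matches, function(x) x$canonical_key, character(1)))]
}

#' Count pattern matches
#' @inheritParams find_matches
#' @return Non-negative integer.
#' @export
count_matches <- function(target, pat) length(find_matches(target, pat))

#' The alley-cropping service pattern: a crop between two tree lines
#'
#' Convenience constructor for the line-crop-line structure supporting pest
#' regulation by natural enemies overwintering in the tree lines.
#'
#' @param strip_width,alley_width,plot_length Geometry of the fragment (m);
#'   face metrics are not constrained unless predicates are added.
#' @param predicates Extra predicates.
#' @return An [pattern()] object with roles `line_a`, `crop`, `line_b`.
#' @export
line_crop_line_pattern <- function(strip_width = 2, alley_width = 12,
                                   plot_length = 24, predicates = list()) {
  spec <- generate_plot(synth_params(n_lines = 2, trees_per_line = 0,
                                     strip_width = strip_width,
                                     alley_width = alley_width,
                                     plot_length = plot_length))
  frag <- build_plot(spec)
  roles <- character(0)
  roles[as.character(face_by_area(frag, "strip1"))] <- "line_a"
  roles[as.character(face_by_area(frag, "alley1"))] <- "crop"
  roles[as.character(face_by_area(frag, "strip2"))] <- "line_b"
  pattern(frag, roles,
          c(list(pred_between("crop", "line_a", "line_b")), predicates))
}
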
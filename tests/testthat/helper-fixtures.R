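# Fixtures and independent oracles, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Open two-triangle map: triangle 1 = darts 1,2,3 (A-B-C), triangle 2 =
# darts 4,5,6 (C-B-X), glued along the B-C edge by beta2(2) = 4. Dart 5 has
# no beta2 image until the border is made explicit.
two_triangle_map <- function() {
  m <- cmap()
  A <- c(0, 0); B <- c(2, 0); C <- c(1, 1); X <- c(2, 1)
  for (p in list(A, B, C)) add_dart(m, p[1], p[2])
  for (p in list(C, B, X)) add_dart(m, p[1], p[2])
  link1(m, 1, 2); link1(m, 2, 3); link1(m, 3, 1)
  link1(m, 4, 5); link1(m, 5, 6); link1(m, 6, 4)
  sew2(m, 2, 4)
  m
}

bordered_two_triangle_map <- function() {
  m <- two_triangle_map()
  make_border_explicit(m)
  m
}

# Two unit squares sharing a full vertical edge, border explicit.
two_squares_map <- function() {
  a <- face_from_polygon(rect_poly(0, 0, 1, 1), "crop", list(area_id = "sq1"))
  b <- face_from_polygon(rect_poly(1, 0, 2, 1), "crop", list(area_id = "sq2"))
  m <- merge_maps(a, b)
  make_border_explicit(m)
  m
}

# The archetypal 2-line / 1-alley / 3-trees-per-line plot.
archetype_plot <- function(...) build_plot(generate_plot(synth_params(...)))

# Deterministic parameter draws for property loops.
random_params <- function(i) {
  withr::with_seed(1000L + i, {
    synth_params(n_lines = sample(2:4, 1),
                 trees_per_line = sample(0:3, 1),
                 strip_width = runif(1, 1.5, 3),
                 alley_width = runif(1, 6, 15),
                 tree_size = runif(1, 0.5, 1.2),
                 plot_length = runif(1, 18, 30),
                 jitter = sample(c(0, 0.2), 1),
                 seed = i)
  })
}

# Independent brute-force pattern matcher: ordered assignment of the
# pattern's role-face darts to target darts with incremental consistency
# checks, then predicate filtering and face-set deduplication. Used as the
# completeness oracle for find_matches on small targets.
brute_match_keys <- function(target, pat) {
  frag <- pat$fragment
  fids <- as.integer(names(pat$roles))
  fdarts <- darts(frag)
  dom <- fdarts[frag$face_of[fdarts] %in% fids & is.na(frag$hole_of[fdarts])]
  tids <- level_darts(target)
  et <- function(m, d) {
    e <- m$props[[d]]$element_type
    if (is.null(e)) NA_character_ else e
  }
  keys <- character(0)
  n <- length(dom)
  assign_next <- function(k, fwd) {
    if (k > n) {
      fm <- integer(0)
      for (fid in fids) {
        sel <- dom[frag$face_of[dom] == fid]
        tf <- unique(target$face_of[fwd[as.character(sel)]])
        if (length(tf) != 1) return(invisible(NULL))
        fm[pat$roles[[as.character(fid)]]] <- tf
      }
      if (anyDuplicated(fm)) return(invisible(NULL))
      if (!agromap:::check_predicates(target, as.list(fm), pat$predicates))
        return(invisible(NULL))
      keys <<- c(keys, paste(sort(fm), collapse = ","))
      return(invisible(NULL))
    }
    p <- dom[k]
    for (t in tids) {
      if (t %in% fwd) next
      if (!identical(et(frag, p), et(target, t))) next
      # consistency with every already-assigned dart
      ok <- TRUE
      for (j in seq_len(k - 1)) {
        q <- dom[j]; u <- fwd[as.character(q)]
        if (frag$b1[q] == p && target$b1[u] != t) { ok <- FALSE; break }
        if (frag$b1[p] == q && target$b1[t] != u) { ok <- FALSE; break }
        if (frag$b2[q] == p && target$b2[u] != t) { ok <- FALSE; break }
        if (frag$b2[p] == q && target$b2[t] != u) { ok <- FALSE; break }
      }
      if (!ok) next
      fwd2 <- fwd; fwd2[as.character(p)] <- t
      assign_next(k + 1, fwd2)
    }
    invisible(NULL)
  }
  assign_next(1L, integer(0))
  sort(unique(keys))
}

# Re-verify a match independently of the search: injectivity, beta1
# preservation, beta2 preservation inside the domain, predicate truth.
verify_match <- function(target, pat, match) {
  frag <- pat$fragment
  dm <- match$dart_map
  dom <- as.integer(names(dm))
  if (anyDuplicated(dm)) return(FALSE)
  for (p in dom) {
    t <- dm[[as.character(p)]]
    if (frag$b1[p] %in% dom &&
        target$b1[t] != dm[[as.character(frag$b1[p])]]) return(FALSE)
    if (frag$b2[p] %in% dom &&
        target$b2[t] != dm[[as.character(frag$b2[p])]]) return(FALSE)
    pe <- frag$props[[p]]$element_type
    te <- target$props[[t]]$element_type
    if (!identical(pe, te)) return(FALSE)
  }
  agromap:::check_predicates(target, match$face_map, pat$predicates)
}
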
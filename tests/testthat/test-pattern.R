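# Attributed pattern matching with metric constraints.

test_that("face metrics: bounding box, hole-subtracted area, multiples", {
  sq <- face_from_polygon(rect_poly(0, 0, 1, 1), "crop")
  make_border_explicit(sq)
  f <- attr(sq, "face_id")
  expect_equal(eval_metric(sq, f, "area"), 1)
  expect_equal(eval_metric(sq, f, "width"), 1)
  expect_equal(eval_metric(sq, f, "height"), 1)
  expect_error(eval_metric(sq, f, "volume"), "unknown metric")

  embed_hole(sq, f, face_from_polygon(rect_poly(0.4, 0.4, 0.6, 0.6), "tree"))
  expect_equal(eval_metric(sq, f, "area"), 0.96)
})

test_that("the line-crop-line pattern is found once in the 2-line plot", {
  pat <- line_crop_line_pattern()
  m <- archetype_plot()
  ms <- find_matches(m, pat)
  expect_identical(length(ms), 1L)
  fm <- ms[[1]]$face_map
  expect_setequal(unlist(fm[c("line_a", "line_b")]),
                  c(face_by_area(m, "strip1"), face_by_area(m, "strip2")))
  expect_identical(fm$crop, face_by_area(m, "alley1"))
  expect_true(verify_match(m, pat, ms[[1]]))
})

test_that("the 3-line plot contains the service pattern twice", {
  pat <- line_crop_line_pattern()
  m <- build_plot(generate_plot(synth_params(n_lines = 3, trees_per_line = 2)))
  ms <- find_matches(m, pat)
  expect_identical(length(ms), 2L)
  for (x in ms) expect_true(verify_match(m, pat, x))
  keys <- vapply(ms, function(x) x$canonical_key, character(1))
  expect_identical(keys, sort(keys))       # deterministic ordering
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("matching a pattern against its own fragment finds the identity embedding", {
  pat <- line_crop_line_pattern()
  expect_identical(count_matches(pat$fragment, pat), 1L)
})

test_that("empty targets and unsatisfiable predicates give zero matches", {
  expect_identical(count_matches(cmap(), line_crop_line_pattern()), 0L)
  pat <- line_crop_line_pattern(predicates = list(
    pred_attr("crop", "no_such_key", "x")))
  expect_identical(count_matches(archetype_plot(), pat), 0L)
})

test_that("metric predicates: alley width as a multiple of the machine width", {
  # plots are 24 m long, so the crop face is 24 m wide: a multiple of 4, not 5
  ok_pat <- line_crop_line_pattern(predicates = list(
    pred_metric("crop", "width", "multiple_of", 4)))
  bad_pat <- line_crop_line_pattern(predicates = list(
    pred_metric("crop", "width", "multiple_of", 5)))
  m <- archetype_plot()
  expect_identical(count_matches(m, ok_pat), 1L)
  expect_identical(count_matches(m, bad_pat), 0L)
  # the alley height (12 m) is a multiple of the 4 m machine, 13 m is not
  m13 <- build_plot(generate_plot(synth_params(alley_width = 13, trees_per_line = 0)))
  hpat4 <- line_crop_line_pattern(predicates = list(
    pred_metric("crop", "height", "multiple_of", 4)))
  expect_identical(count_matches(m, hpat4), 1L)
  expect_identical(count_matches(m13, hpat4), 0L)
})

test_that("adding predicates never increases the match count", {
  m <- build_plot(generate_plot(synth_params(n_lines = 4, trees_per_line = 1)))
  base <- line_crop_line_pattern()
  n0 <- count_matches(m, base)
  preds <- list(pred_adjacent("line_a", "crop"),
                pred_metric("crop", "height", ">=", 6),
                pred_attr("crop", "no_such", 1))
  acc <- list()
  for (p in preds) {
    acc <- c(acc, list(p))
    n1 <- count_matches(m, line_crop_line_pattern(predicates = acc))
    expect_lte(n1, n0)
    n0 <- n1
  }
})

test_that("the search is anchor-independent", {
  pat <- line_crop_line_pattern()
  m <- build_plot(generate_plot(synth_params(n_lines = 3, trees_per_line = 0)))
  dom <- agromap:::pattern_domain(pat)
  ref <- vapply(find_matches(m, pat), function(x) x$canonical_key, character(1))
  for (a in dom) {
    keys <- vapply(find_matches(m, pat, anchor = a),
                   function(x) x$canonical_key, character(1))
    expect_identical(keys, ref)
  }
})

test_that("find_matches agrees with brute-force enumeration on a small target", {
  # single strip-crop pattern against the treeless 2-line plot (20 darts)
  frag <- build_plot(generate_plot(synth_params(trees_per_line = 0)))
  roles <- character(0)
  roles[as.character(face_by_area(frag, "strip1"))] <- "line"
  roles[as.character(face_by_area(frag, "alley1"))] <- "crop"
  pat <- pattern(frag, roles)
  m <- build_plot(generate_plot(synth_params(n_lines = 2, trees_per_line = 0)))
  got <- vapply(find_matches(m, pat), function(x) x$canonical_key, character(1))
  expect_identical(got, brute_match_keys(m, pat))
  expect_identical(length(got), 2L)   # strip1-crop and strip2-crop
})
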
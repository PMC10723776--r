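# Kernel: dart management, beta operators, orbits, validation, copying.

test_that("dart ids are consecutive in creation order and never reused", {
  m <- cmap()
  ids <- c(add_dart(m, 0, 0), add_dart(m, 1, 0), add_dart(m, 1, 1))
  expect_identical(ids, 1:3)

  m2 <- cmap()
  add_dart(m2, 0, 0)
  remove_dart(m2, 1)
  expect_identical(darts(m2), integer(0))
  expect_identical(add_dart(m2, 5, 5), 2L)   # id 1 is gone for good
})

test_that("removing a dart unsets incoming links and validate reports the gaps", {
  m <- bordered_two_triangle_map()
  expect_true(validate_map(m)$ok)
  remove_dart(m, 2)
  rep <- validate_map(m)
  expect_false(rep$ok)
  rules <- vapply(rep$violations, function(v) v$rule, character(1))
  expect_true("beta1-totality" %in% rules)
  expect_identical(rep$violations[[which(rules == "beta1-totality")]]$darts, 1L)
  expect_true("beta2-totality" %in% rules)
  expect_identical(rep$violations[[which(rules == "beta2-totality")]]$darts, 4L)
})

test_that("link1 semantics: relinking overwrites, self-loops are legal faces", {
  m <- cmap()
  add_dart(m, 0, 0); add_dart(m, 1, 0); add_dart(m, 0, 1)
  link1(m, 1, 2)
  expect_identical(beta1(m, 1), 2L)
  link1(m, 1, 3)
  expect_identical(beta1(m, 1), 3L)

  s <- cmap()
  add_dart(s, 0, 0)
  link1(s, 1, 1)
  expect_identical(orbit_face(s, 1), 1L)
})

test_that("sew2 is a fixed-point-free involution, idempotent on a sewn pair", {
  m <- two_triangle_map()
  expect_identical(beta2(m, 2), 4L)
  expect_identical(beta2(m, 4), 2L)
  expect_identical(beta2(m, beta2(m, 2)), 2L)
  expect_silent(sew2(m, 2, 4))                 # idempotent
  expect_error(sew2(m, 1, 1), "fixed-point")
  expect_error(sew2(m, 2, 5), "already")       # 2 is sewn to 4
  sew2(m, 2, 5, force = TRUE)
  expect_identical(beta2(m, 2), 5L)
  expect_true(is.na(beta2(m, 4)))
})

test_that("face orbits follow beta1 and fail on open chains", {
  m <- two_triangle_map()
  expect_identical(beta1(m, 1), 2L)
  expect_identical(orbit_face(m, 2), c(2L, 3L, 1L))
  expect_identical(beta1(m, 4), 5L)

  open_m <- cmap()
  add_dart(open_m, 0, 0); add_dart(open_m, 1, 0)
  link1(open_m, 1, 2)
  expect_error(orbit_face(open_m, 1), "face not closed")
})

test_that("the explicit border of the two-triangle map has 4 darts, orbit length 4", {
  m <- two_triangle_map()
  n0 <- n_darts(m)
  make_border_explicit(m)
  expect_identical(n_darts(m) - n0, 4L)
  expect_true(validate_map(m)$ok)
  border <- setdiff(darts(m), 1:6)
  expect_identical(length(orbit_face(m, border[1])), 4L)
  counts <- map_counts(m)
  expect_identical(unname(counts), c(4, 5, 3, 2))  # V, E, F, Euler
})

test_that("orbit_node alternates beta1 then beta2 and matches the worked chains", {
  m <- two_triangle_map()
  expect_identical(orbit_node(m, 1), c(1L, 2L, 4L, 5L))   # truncated: beta2(5) unset

  # smallest closed map: a loop edge made of two self-loop darts
  s <- cmap()
  add_dart(s, 0, 0); add_dart(s, 0, 0)
  link1(s, 1, 1); link1(s, 2, 2); sew2(s, 1, 2)
  expect_true(validate_map(s)$ok)
  expect_identical(orbit_node(s, 1), c(1L, 2L))

  # at a junction of 3 edges the node orbit has 6 darts
  m2 <- two_squares_map()
  heads <- vapply(darts(m2), function(d) {
    h <- agromap:::dart_head(m2, d); all(abs(h - c(1, 0)) < 1e-9)
  }, logical(1))
  d0 <- darts(m2)[heads][1]
  expect_identical(length(orbit_node(m2, d0)), 6L)
})

test_that("vertex orbits partition the darts and count the nodes", {
  m <- bordered_two_triangle_map()
  orbs <- vertex_orbits(m)
  expect_identical(length(orbs), 4L)                       # V = 2 - F + E = 4
  expect_setequal(unlist(orbs), darts(m))
  expect_identical(sum(lengths(orbs)), length(darts(m)))   # pairwise disjoint

  sq <- face_from_polygon(rect_poly(0, 0, 1, 1), "crop")
  make_border_explicit(sq)
  expect_identical(length(vertex_orbits(sq)), 4L)
  # all darts in one vertex orbit share their origin
  for (orb in vertex_orbits(sq)) {
    o <- dart_origin(sq, orb)
    expect_lt(max(abs(sweep(o, 2, o[1, ]))), 1e-9)
  }
})

test_that("orbit_custom composes right-to-left and errors name the failing step", {
  m <- two_triangle_map()
  expect_identical(orbit_custom(m, 2, c("beta1", "beta1", "beta1")), 2L)
  expect_identical(orbit_custom(m, 3, character(0)), 3L)
  b <- bordered_two_triangle_map()
  for (d in darts(b))
    expect_identical(orbit_custom(b, d, c("beta2", "beta2")), d)
  expect_error(orbit_custom(m, 1, c("beta2")), "beta2 is unset at dart 1")
})

test_that("validate reports beta2 totality and involution failures", {
  m <- two_triangle_map()
  rep <- validate_map(m)
  expect_false(rep$ok)
  rules <- vapply(rep$violations, function(v) v$rule, character(1))
  expect_identical(rules, "beta2-totality")
  expect_identical(rep$violations[[1]]$darts, c(1L, 3L, 5L, 6L))

  # beta2(a) = b but beta2(b) = c is an involution violation
  k <- cmap()
  for (i in 1:3) add_dart(k, i, 0)
  k$b2[1] <- 2L; k$b2[2] <- 3L; k$b2[3] <- 2L
  rules2 <- vapply(validate_map(k)$violations, function(v) v$rule, character(1))
  expect_true("beta2-involution" %in% rules2)
})

test_that("geometric coherence violations are caught", {
  m <- bordered_two_triangle_map()
  m$x[2] <- m$x[2] + 1  # displace one origin: its predecessors disagree
  rules <- vapply(validate_map(m)$violations, function(v) v$rule, character(1))
  expect_true("geometric-coherence" %in% rules)
})

test_that("copy_map is deep: mutating the copy leaves the original intact", {
  m <- bordered_two_triangle_map()
  cp <- copy_map(m)
  expect_identical(cp$b1, m$b1)
  expect_identical(cp$b2, m$b2)
  expect_identical(as.character(serialize_map(cp)), as.character(serialize_map(m)))
  remove_dart(cp, 2)
  expect_true(validate_map(m)$ok)
  expect_false(validate_map(cp)$ok)
})
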
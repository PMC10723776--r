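# Incremental plot construction: polygon faces, merging, holes, the
# explicit border and the full build pipeline.

test_that("face_from_polygon builds a closed 2-face fragment with the right orientation", {
  m <- face_from_polygon(rect_poly(0, 0, 1, 1), "crop")
  expect_identical(n_darts(m), 8L)
  orbs <- face_orbits(m)
  expect_identical(lengths(orbs), c(4L, 4L))
  expect_true(validate_map(m)$ok)
  fid <- attr(m, "face_id")
  expect_gt(signed_area(face_polygon(m, fid)), 0)
  comp <- setdiff(faces(m), fid)
  expect_lt(signed_area(dart_origin(m, orbit_face(m, get_face(m, comp)$anchor))), 0)

  # clockwise input is normalized to counterclockwise
  cw <- rect_poly(0, 0, 1, 1)[4:1, ]
  m2 <- face_from_polygon(cw, "crop")
  expect_gt(signed_area(face_polygon(m2, attr(m2, "face_id"))), 0)

  tri <- face_from_polygon(rbind(c(0, 0), c(2, 0), c(1, 1)), "crop")
  expect_identical(length(orbit_face(tri, get_face(tri, attr(tri, "face_id"))$anchor)), 3L)

  expect_error(face_from_polygon(rbind(c(0, 0), c(1, 0)), "crop"), "3 distinct")
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(face_from_polygon(bow, "crop"), "not simple")
})

test_that("merging two squares along a shared edge gives V=6, E=7, F=3", {
  m <- two_squares_map()
  counts <- map_counts(m)
  expect_identical(unname(counts), c(6, 7, 3, 2))
  expect_true(validate_map(m)$ok)
})

test_that("merge is identity against an empty map and rejects T-junctions", {
  a <- face_from_polygon(rect_poly(0, 0, 1, 1), "crop")
  s0 <- as.character(serialize_map(a))
  out <- merge_maps(a, cmap())
  expect_identical(as.character(serialize_map(out)), s0)

  # half-height neighbour: its edge covers only part of the square's edge
  b <- face_from_polygon(rect_poly(1, 0, 2, 0.5), "crop")
  expect_error(merge_maps(a, b), "non-conforming")
})

test_that("embedding children creates holes, strictness enforced", {
  spec <- generate_plot(synth_params())
  m <- build_plot(spec)
  s1 <- face_by_area(m, "strip1")
  expect_identical(length(face_holes(m, s1)), 3L)   # 3 trees per line
  for (h in face_holes(m, s1)) expect_identical(face_parent(m, h), s1)

  # child touching the parent border is refused
  frag <- face_from_polygon(rect_poly(0, 0.5, 1, 1.5), "tree")
  expect_error(embed_hole(m, s1, frag), "strictly inside")
  # hole cycle length equals the filling border length, beta2-sewn pairwise
  h1 <- face_holes(m, s1)[1]
  anchor <- Filter(function(x) x$child == h1, get_face(m, s1)$holes)[[1]]$anchor
  hole_cycle <- orbit_face(m, anchor)
  fill_cycle <- orbit_face(m, get_face(m, h1)$anchor)
  expect_identical(length(hole_cycle), length(fill_cycle))
  expect_setequal(beta2(m, hole_cycle), fill_cycle)
})

test_that("make_border_explicit is idempotent and the 3-rectangle outline has 8 border darts", {
  m <- archetype_plot()
  s0 <- as.character(serialize_map(m))
  make_border_explicit(m)
  expect_identical(as.character(serialize_map(m)), s0)

  out_f <- Filter(function(f) identical(face_element_type(m, f), "outside"), faces(m))
  expect_identical(length(out_f), 1L)
  expect_identical(length(orbit_face(m, get_face(m, out_f[[1]])$anchor)), 8L)
})

test_that("build_plot assembles the archetypal 2-line system correctly", {
  m <- archetype_plot()
  expect_true(validate_map(m)$ok)
  top <- faces(m, top_only = TRUE)
  expect_identical(length(top), 4L)   # 2 strips + 1 crop + outside
  types <- sort(vapply(top, function(f) face_element_type(m, f), character(1)))
  expect_identical(types, c("crop", "outside", "understory_strip", "understory_strip"))
  # every dart carries the element type of its incident face
  for (d in darts(m))
    expect_identical(m$props[[d]]$element_type,
                     face_element_type(m, face_of_dart(m, d)))
  # interior on the left: interior faces counterclockwise, outside clockwise
  for (f in top) {
    a <- signed_area(face_polygon(m, f))
    if (identical(face_element_type(m, f), "outside")) expect_lt(a, 0)
    else expect_gt(a, 0)
  }
  # areas add up to the outline
  expect_equal(map_area(m), 24 * (2 + 12 + 2), tolerance = 1e-9)
})

test_that("build_plot is deterministic and rejects empty specs", {
  expect_error(plot_spec(list()) |> build_plot(), "empty")
  s1 <- as.character(serialize_map(archetype_plot()))
  s2 <- as.character(serialize_map(archetype_plot()))
  expect_identical(s1, s2)
})

test_that("Euler holds at the embedded level of each strip", {
  m <- archetype_plot()
  for (sid in c("strip1", "strip2")) {
    f <- face_by_area(m, sid)
    lvl <- level_darts(m, f)
    # each hole/filling pair is a closed 2-face sub-map: Euler 2 per tree
    counts <- map_counts(m, lvl)
    n_trees <- length(face_holes(m, f))
    expect_identical(unname(counts["euler"]), 2 * n_trees)
  }
})
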
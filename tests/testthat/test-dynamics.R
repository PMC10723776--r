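# Dynamics: attribute evolution, crown growth, planting and thinning.

test_that("set_attributes never touches the beta structure", {
  m <- archetype_plot()
  t1 <- face_by_area(m, "tree1_1")
  h0 <- structural_hash(m)
  set_attributes(m, face = t1, updates = list(crown_radius = 1.5))
  expect_identical(face_attributes(m, t1)$crown_radius, 1.5)
  expect_identical(structural_hash(m), h0)
  expect_true(validate_map(m)$ok)
  d0 <- darts(m)[1]
  set_attributes(m, dart = d0, updates = list(flux = 0.3))
  expect_identical(m$props[[d0]]$flux, 0.3)
  expect_identical(structural_hash(m), h0)
})

test_that("crown growth across the strip-crop border splits the tree over both faces", {
  m <- archetype_plot()
  a0 <- map_area(m)
  t1 <- face_by_area(m, "tree1_1")
  crop <- face_by_area(m, "alley1")
  expect_false(any(vapply(interfaces(m), function(it)
    crop %in% c(it$face_a, it$face_b) &&
      any(vapply(c(it$face_a, it$face_b), function(f)
        identical(face_attributes(m, f)$group, t1) ||
          identical(face_attributes(m, f)$tree_id, t1), logical(1))),
    logical(1))))
  tb <- poly_bbox(face_polygon(m, t1))
  it0 <- vapply(interfaces(m), function(x) paste(x$face_a, x$face_b), character(1))
  grow_crown(m, t1, c(tb["xmin"] - 0.2, tb["xmax"] + 0.2, tb["ymin"], 4.5),
             label = "year10")
  expect_true(validate_map(m)$ok)
  nf <- attr(m, "new_faces")
  expect_identical(length(nf), 2L)
  types <- vapply(nf, function(f) face_element_type(m, f), character(1))
  expect_setequal(types, c("tree", "mixed"))
  # both crown parts carry the common group id; the mixed part carries crop provenance
  for (f in nf) expect_identical(face_attributes(m, f)$group, t1)
  mixed <- nf[types == "mixed"]
  expect_identical(face_attributes(m, mixed)$crop_id, crop)
  # a tree-crop interface now exists in the dual: the canopy face over the
  # crop is adjacent to the crop, and to the tree part on the strip
  expect_true(faces_adjacent(m, mixed, crop))
  expect_true(faces_adjacent(m, mixed, nf[types == "tree"]))
  # growth is monotone in adjacency and conserves area
  it1 <- vapply(interfaces(m), function(x) paste(x$face_a, x$face_b), character(1))
  expect_true(all(it0 %in% it1))
  expect_equal(map_area(m), a0, tolerance = 1e-6)
})

test_that("a crown still inside its strip changes no top-level structure", {
  m <- archetype_plot()
  n_top <- length(faces(m, top_only = TRUE))
  t2 <- face_by_area(m, "tree1_2")
  tb <- poly_bbox(face_polygon(m, t2))
  grow_crown(m, t2, c(tb["xmin"] - 0.1, tb["xmax"] + 0.1,
                      tb["ymin"] - 0.1, tb["ymax"] + 0.1))
  expect_true(validate_map(m)$ok)
  expect_identical(length(faces(m, top_only = TRUE)), n_top)
  expect_equal(map_area(m), 24 * 16, tolerance = 1e-9)
})

test_that("a shrinking crown or an escaping crown is refused", {
  m <- archetype_plot()
  t1 <- face_by_area(m, "tree1_1")
  tb <- poly_bbox(face_polygon(m, t1))
  expect_error(grow_crown(m, t1, c(tb["xmin"] + 0.2, tb["xmax"], tb["ymin"], tb["ymax"])),
               "contain the old crown")
  expect_error(grow_crown(m, t1, c(tb["xmin"], tb["xmax"], -1, tb["ymax"])),
               "escap|overlay")
})

test_that("thinning an embedded tree restores a hole-free region, Euler intact", {
  m <- archetype_plot()
  s1 <- face_by_area(m, "strip1")
  t1 <- face_by_area(m, "tree1_1")
  remove_element(m, t1)
  expect_true(validate_map(m)$ok)
  expect_identical(length(face_holes(m, s1)), 2L)
  expect_identical(unname(map_counts(m, level_darts(m))["euler"]), 2)
  expect_identical(unname(map_counts(m, level_darts(m, s1))["euler"]), 4)  # 2 trees left
  expect_error(remove_element(m, Filter(function(f)
    identical(face_element_type(m, f), "outside"), faces(m))[[1]]),
    "outside")
})

test_that("remove then re-add an element recovers the original map up to renumbering", {
  m <- archetype_plot()
  c0 <- canonical_form(m)
  t1 <- face_by_area(m, "tree1_1")
  poly <- face_polygon(m, t1)
  at <- face_attributes(m, t1)
  pa <- face_parent(m, t1)
  remove_element(m, t1)
  expect_false(identical(canonical_form(m), c0))
  add_element(m, pa, poly, "tree", at)
  expect_identical(canonical_form(m), c0)
  expect_true(map_isomorphic(m, archetype_plot()))
})

test_that("planting works on strips and directly on the crop (scattered trees)", {
  m <- archetype_plot()
  s1 <- face_by_area(m, "strip1")
  add_element(m, s1, rect_poly(21.5, 0.6, 22.5, 1.4), "tree", list(rank = 4))
  expect_identical(length(face_holes(m, s1)), 4L)
  crop <- face_by_area(m, "alley1")
  f <- add_element(m, crop, rect_poly(10, 7, 11, 8), "tree", list(scattered = TRUE))
  expect_identical(face_parent(m, f), crop)
  expect_true(validate_map(m)$ok)
})

test_that("top-level removal merges the face into a named neighbour", {
  m <- build_plot(generate_plot(synth_params(trees_per_line = 0)))
  al <- face_by_area(m, "alley1")
  s1 <- face_by_area(m, "strip1")
  remove_element(m, al, into = s1)
  expect_true(validate_map(m)$ok)
  expect_identical(length(faces(m, top_only = TRUE)), 3L)
  expect_equal(map_area(m), 24 * 16, tolerance = 1e-9)
  expect_equal(abs(signed_area(face_polygon(m, s1))), 24 * 14, tolerance = 1e-9)
})

test_that("scripted event sequences from JSON lines keep the map valid", {
  m <- archetype_plot()
  t1 <- face_by_area(m, "tree1_1")
  tb <- poly_bbox(face_polygon(m, t1))
  crown <- rbind(c(tb["xmin"] - 0.2, tb["ymin"]), c(tb["xmax"] + 0.2, tb["ymin"]),
                 c(tb["xmax"] + 0.2, 4.0), c(tb["xmin"] - 0.2, 4.0))
  evf <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    jsonlite::toJSON(list(op = "set", face = face_by_area(m, "alley1"),
                          updates = list(species = "wheat")), auto_unbox = TRUE),
    jsonlite::toJSON(list(op = "remove", face = face_by_area(m, "tree2_1")),
                     auto_unbox = TRUE),
    jsonlite::toJSON(list(op = "add", parent = face_by_area(m, "strip2"),
                          polygon = unname(apply(rect_poly(3, 14.6, 4, 15.4), 1, c,
                                                 simplify = FALSE)),
                          element_type = "tree", attributes = list(rank = 1)),
                     auto_unbox = TRUE),
    jsonlite::toJSON(list(op = "grow", tree = t1,
                          crown = unname(apply(crown, 1, c, simplify = FALSE)),
                          label = "y5"), auto_unbox = TRUE)
  ), evf)
  apply_events(m, read_events(evf))
  expect_true(validate_map(m)$ok)
  expect_identical(face_attributes(m, face_by_area(m, "alley1"))$species, "wheat")
  expect_equal(map_area(m), 24 * 16, tolerance = 1e-6)
})
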
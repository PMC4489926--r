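test_that("Alexander determinants reproduce the published values", {
  # no crossings: unknot
  tri <- closed_polygon(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(unname(alexander_determinants(tri)), c(1, 1))
  # parametric fixtures against |Delta(-1)|, |Delta(-2)| of the published
  # polynomials: 3_1 t^2-t+1, 4_1 -t^2+3t-1, 5_1 t^4-t^3+t^2-t+1,
  # 5_2 2t^2-3t+2
  expected <- list("3_1" = c(3, 7), "4_1" = c(5, 11),
                   "5_1" = c(5, 31), "5_2" = c(7, 16))
  for (lab in names(expected)) {
    poly <- kmt_simplify(parametric_knot(lab, 240))
    expect_equal(unname(alexander_determinants(poly)), expected[[lab]],
                 info = lab)
  }
})

test_that("classification is a deterministic table lookup", {
  expect_equal(classify_knot(c(1, 1)), "0_1")
  expect_equal(classify_knot(c(3, 7)), "3_1")
  expect_equal(classify_knot(c(5, 11)), "4_1")
  expect_equal(classify_knot(c(5, 31)), "5_1")
  expect_equal(classify_knot(c(7, 16)), "5_2")
  expect_equal(classify_knot(c(9, 40)), "other")
  expect_equal(classify_knot(c(3, 8)), "other")
})

test_that("geometric simplification collapses trivial polygons", {
  # planar convex 100-gon reduces to a triangle
  t <- seq(0, 2 * pi, length.out = 101)[-101]
  poly <- closed_polygon(cbind(cos(t), sin(t), 0 * t))
  red <- kmt_simplify(poly)
  expect_equal(nrow(red$vertices), 3)
  # an already minimal triangle is a fixed point
  tri <- closed_polygon(rbind(c(0, 0, 0), c(1, 0.2, 0), c(0.3, 1, 0.1)))
  expect_equal(kmt_simplify(tri)$vertices, tri$vertices)
})

test_that("simplification preserves the knot type", {
  tre <- parametric_knot("3_1", 200)
  red <- kmt_simplify(tre)
  expect_gte(nrow(red$vertices), 6) # a trefoil needs at least 6 sticks
  expect_lt(nrow(red$vertices), 30)
  expect_equal(classify_polygon(tre, simplify = FALSE)$label, "3_1")
  expect_equal(classify_polygon(red, simplify = FALSE)$label, "3_1")
  # random closed polygons: classification before and after reduction
  for (seed in 1:25) {
    poly <- random_closed_polygon(60, seed = seed)
    direct <- classify_polygon(poly, simplify = FALSE, seed = seed)
    reduced <- classify_polygon(poly, simplify = TRUE, seed = seed + 1000)
    expect_identical(direct$label, reduced$label, info = paste("seed", seed))
    expect_equal(direct$det_minus1, reduced$det_minus1)
    expect_equal(direct$det_minus2, reduced$det_minus2)
  }
})

test_that("determinants are projection and orientation invariant", {
  for (lab in c("3_1", "4_1", "5_1", "5_2")) {
    poly <- kmt_simplify(parametric_knot(lab, 200, noise_amplitude = 0.03,
                                         seed = 5))
    base <- alexander_determinants(poly, seed = 1)
    for (s in 2:21)
      expect_equal(alexander_determinants(poly, seed = s), base,
                   info = paste(lab, "projection", s))
    # reversing the vertex order never changes the classification
    rev_poly <- closed_polygon(poly$vertices[nrow(poly$vertices):1, ])
    expect_equal(unname(alexander_determinants(rev_poly, seed = 3)),
                 unname(base), info = paste(lab, "reversed"))
  }
})

test_that("parametric fixtures classify correctly under noise", {
  counts <- c("0_1" = 0, "3_1" = 0, "4_1" = 0, "5_1" = 0, "5_2" = 0)
  for (lab in names(counts)) {
    nv <- if (lab == "0_1") 50 else 220
    for (s in 1:20) {
      poly <- parametric_knot(lab, nv, noise_amplitude = 0.05, seed = s)
      got <- classify_polygon(poly, seed = s)$label
      counts[lab] <- counts[lab] + (got == lab)
    }
  }
  expect_equal(unname(counts), rep(20, 5))
  # vertex budget precondition
  expect_error(parametric_knot("5_1", 10), "vertices")
})

test_that("chain closure keeps marks and requires circularization", {
  p <- model_params(n_beads = 30, sticky_internal_pair = c(8L, 22L))
  o <- run_until_circularization(p, run_protocol(seed = 17, max_steps = 2e6))
  expect_true(o$circularized)
  poly <- close_chain(o)
  expect_equal(nrow(poly$vertices), 30)
  expect_equal(poly$marked, c(8L, 22L))
  # marks survive simplification at the same bead coordinates
  red <- kmt_simplify(poly)
  expect_equal(red$vertices[red$marked[1], ], poly$vertices[8, ])
  expect_equal(red$vertices[red$marked[2], ], poly$vertices[22, ])
})

test_that("loop relevance distinguishes localized from entangled knots", {
  # knot tied entirely inside the sticky loop: excision unknots the ring
  # but the knot is localized, hence irrelevant
  inside <- spliced_trefoil_polygon("knot")
  expect_equal(classify_polygon(inside)$label, "3_1")
  r1 <- loop_relevance(inside, "3_1")
  expect_equal(as.character(r1), "irrelevant")
  expect_equal(unname(attr(r1, "sub_labels")["loop"]), "3_1")
  # knot in the complementary loop (sticky loop on the detour): excision
  # leaves the trefoil intact, hence irrelevant
  outside <- spliced_trefoil_polygon("detour")
  r2 <- loop_relevance(outside, "3_1")
  expect_equal(as.character(r2), "irrelevant")
  expect_equal(unname(attr(r2, "sub_labels")["excised"]), "3_1")
  # marks placed across the knotted core: excision destroys the knot and
  # neither sub-ring carries it, hence relevant (loop entangled with knot)
  tre <- parametric_knot("3_1", 120)
  across <- closed_polygon(tre$vertices, marked = c(30L, 90L))
  r3 <- loop_relevance(across, "3_1")
  expect_equal(as.character(r3), "relevant")
  # unknotted input is a precondition violation
  expect_error(loop_relevance(inside, "0_1"), "knotted")
})

test_that("loop closure flag agrees with the final-frame distance", {
  p <- model_params(n_beads = 40, sticky_internal_pair = c(12L, 28L))
  agree <- 0; n_ok <- 0
  for (s in 1:12) {
    pr <- run_protocol(seed = 400 + s, max_steps = 3e6)
    o <- run_until_circularization(p, pr)
    if (!o$circularized) next
    n_ok <- n_ok + 1
    d <- sqrt(sum((o$final_positions[12, ] - o$final_positions[28, ])^2))
    agree <- agree + (loop_closed(o, p, pr) == (d <= pr$capture_distance))
  }
  expect_gt(n_ok, 0)
  expect_equal(agree, n_ok)
})
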
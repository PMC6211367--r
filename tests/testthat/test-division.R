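test_that("mean target area follows the PMF interpolation and region rules", {
  dps <- division_params("subepidermis")
  dpe <- division_params("epidermis")
  # before onset everything is A_min
  expect_equal(mean_target_area(0.1, 1, "lamina", dps, t = 100), 150)
  # lamina interpolation endpoints and midpoint
  expect_equal(mean_target_area(0.6, 1, "lamina", dps, t = 120), 150)
  expect_equal(mean_target_area(dps$pmf_min, 1, "lamina", dps, t = 120), 300)
  expect_equal(mean_target_area((0.51 + 0.295) / 2, 1, "lamina", dpe, 120),
               225)
  # midline rules: epidermis constant, subepidermis scaled by PGRAD
  expect_equal(mean_target_area(0.4, 1, "midline", dpe, 120), 500)
  expect_equal(mean_target_area(0.4, 1, "midline", dps, 120), 750)
  expect_equal(mean_target_area(0.4, 0.8, "midline", dps, 120), 600)
  # division-threshold mutant shifts the lamina target
  expect_equal(mean_target_area(0.6, 1, "lamina", dps, 120, a_prime = -85),
               65)
})

test_that("sampled targets have the stated moments and are reproducible", {
  set.seed(42)
  a <- sample_target(rep(150, 1e4))
  expect_equal(mean(a), 150, tolerance = 1 / 150)
  expect_equal(sd(a), 30, tolerance = 1 / 30)
  expect_equal(sample_target(c(150, 500), sigma_frac = 0), c(150, 500))
  set.seed(7); x1 <- sample_target(rep(200, 5))
  set.seed(7); x2 <- sample_target(rep(200, 5))
  expect_identical(x1, x2)
})

test_that("competence combines the PMF, PGRAD and LATE gates", {
  dps <- division_params("subepidermis")
  dpe <- division_params("epidermis")
  expect_true(update_competence(0.2, 1, "lamina", late_factor(150), dps))
  expect_false(update_competence(0.1, 1, "lamina", late_factor(150), dps))
  # epidermal PGRAD gate
  expect_false(update_competence(0.9, 0.5, "lamina", 0, dpe))
  expect_true(update_competence(0.9, 0.7, "lamina", 0, dpe))
  # global arrest at LATE >= 0.1680 (t >= 183 h)
  expect_false(update_competence(0.9, 1, "lamina", late_factor(183), dps))
  # midline arrests earlier in the epidermis
  l170 <- late_factor(170)
  expect_false(update_competence(0.9, 1, "midline", l170, dpe))
  expect_true(update_competence(0.9, 1, "lamina", l170, dpe))
})

test_that("the noiseless shortest wall bisects simple shapes", {
  # 2 x 1 rectangle: wall of length 1 across the long axis
  P <- unit_rect(2, 1)
  w <- errera_wall(P, noise_frac = 0, shorten_frac = 0)
  expect_equal(sqrt(sum((w$p_p - w$p_m)^2)), 1, tolerance = 1e-6)
  expect_equal(sort(c(w$p_m[1], w$p_p[1])), c(1, 1), tolerance = 1e-6)
  # regular hexagon: wall joins midpoints of opposite edges
  H <- regular_polygon(6)
  wh <- errera_wall(H, noise_frac = 0, shorten_frac = 0)
  len <- sqrt(sum((wh$p_p - wh$p_m)^2))
  expect_equal(len, sqrt(3), tolerance = 1e-4)   # apothem * 2
  mids <- (H + H[c(2:6, 1), ]) / 2
  d_m <- min(sqrt(rowSums((mids - matrix(wh$p_m, 6, 2, TRUE))^2)))
  expect_lt(d_m, 1e-3)
})

test_that("division conserves area to 1e-9 and updates all neighbours", {
  set.seed(11)
  tis <- leafdyn:::flat_brick_tissue(100, 100, 4, 4)
  dp <- division_params("epidermis")
  for (rep in 1:12) {
    cid <- sample(which(tis$alive), 1)
    a0 <- leafdyn:::polygon_area(tis$vt_pos[tis$cells[[cid]], ])
    res <- leafdyn:::divide_cell(tis, cid, 1, function(cen, region) 150, dp)
    expect_false(is.null(res))
    a1 <- leafdyn:::polygon_area(tis$vt_pos[tis$cells[[res[1]]], ])
    a2 <- leafdyn:::polygon_area(tis$vt_pos[tis$cells[[res[2]]], ])
    expect_equal(a1 + a2, a0, tolerance = 1e-9)
    expect_gt(min(a1, a2), 0)
  }
  # tissue still tiles the rectangle exactly
  tot <- sum(leafdyn:::cell_areas(tis)[tis$alive])
  expect_equal(tot, 100 * 100, tolerance = 1e-9)
})

test_that("threshold crossing gates division; competence gates everything", {
  tis <- leafdyn:::flat_brick_tissue(100, 100, 3, 3)
  dp <- division_params("epidermis")
  areas <- leafdyn:::cell_areas(tis)
  tis$target <- rep(1e6, length(tis$cells))   # unreachable
  tis$competent <- rep(TRUE, length(tis$cells))
  leafdyn:::attempt_divisions(tis, 1, function(cen, region) 150, dp)
  expect_equal(length(tis$events), 0L)
  # non-competent cells never divide regardless of size
  tis$target <- rep(1, length(tis$cells))
  tis$competent <- rep(FALSE, length(tis$cells))
  leafdyn:::attempt_divisions(tis, 2, function(cen, region) 150, dp)
  expect_equal(length(tis$events), 0L)
  # competent + above threshold divides once per step
  n0 <- sum(tis$alive)
  tis$competent <- rep(TRUE, length(tis$cells))
  leafdyn:::attempt_divisions(tis, 3, function(cen, region) 150, dp)
  expect_equal(sum(tis$alive), 2 * n0)
  expect_equal(length(tis$events), n0)
})

test_that("mean area at execution converges to the mean target", {
  # uniform threshold; cells start below threshold, fine time step to
  # limit crossing overshoot; the first hours are discarded (cells whose
  # sampled threshold fell below their starting area execute late)
  ds <- parametric_generate(width = 150, height = 150, n_cu = 14,
                            n_cv = 14, k_x = 0.015, k_y = 0.015,
                            abar_fun = function(x, y) 150,
                            t_end = 45, sampling_interval = 45,
                            seed = 5, dt = 0.5)
  ev <- attr(ds, "ground_truth")$events
  ev <- ev[ev$time > 10, ]
  expect_gt(nrow(ev), 200)
  sem <- sd(ev$mother_area) / sqrt(nrow(ev))
  expect_lt(abs(mean(ev$mother_area) - 150), max(2 * sem, 3))
})

test_that("intercellular spaces start at 2 um^2 and grow at 2.5% per hour", {
  cv <- build_initial_canvas(leaf_geometry(n_u = 10, n_v = 16))
  set.seed(3)
  tis <- init_tissue(cv, model_variant("subepidermis_early"), 5, 8)
  total0 <- sum(leafdyn:::cell_areas(tis)[tis$alive])
  elig <- leafdyn:::eligible_space_vertices(tis)
  expect_gt(length(elig), 10)
  ok <- leafdyn:::replace_vertex_with_space(tis, elig[5], t = 120)
  expect_true(ok)
  a0 <- leafdyn:::space_areas(tis)
  expect_equal(a0, 2, tolerance = 1e-6)
  # cells + spaces still tile the canvas
  tot <- sum(leafdyn:::cell_areas(tis)[tis$alive]) + sum(a0)
  expect_equal(tot, total0, tolerance = 1e-6)
  # autonomous expansion: 10 one-hour steps, static canvas
  for (i in 1:10) leafdyn:::advance_spaces(tis, 1)
  expect_equal(leafdyn:::space_areas(tis) / a0, exp(0.25), tolerance = 0.01)
  # instantaneous areal rate 2.5%/h in the small-step limit
  r0 <- leafdyn:::space_areas(tis)
  leafdyn:::advance_spaces(tis, 0.001)
  expect_equal((leafdyn:::space_areas(tis) / r0 - 1) / 0.001, 0.025,
               tolerance = 1e-3)
})
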
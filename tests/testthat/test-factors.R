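test_that("pro and inh evaluate the printed response functions", {
  expect_equal(pro(0.7, 0), 1)
  expect_equal(pro(0.7, 1), 1.7)
  expect_equal(pro(0.9, 0.295), 1.2655)
  expect_equal(inh(2.2, 0), 1)
  expect_equal(inh(2.2, 1), 1 / 3.2)
  expect_equal(inh(1.0, 1), 0.5)
  expect_error(pro(-1, 1))
})

test_that("LATE follows the piecewise schedule with continuous branches", {
  expect_equal(late_factor(100), 0)
  expect_equal(late_factor(183), 0.1680)
  expect_equal(late_factor(164), 0.0768)
  # exponential branch continuous at 189 h and equal to g_late * 41
  expect_equal(late_factor(189, exponential = TRUE), 0.0048 * 41)
  expect_equal(late_factor(189 - 1e-9, exponential = TRUE),
               late_factor(189 + 1e-9, exponential = TRUE),
               tolerance = 1e-6)
  # nondecreasing for every variant and timing shift
  tt <- seq(0, 420, by = 0.5)
  for (tp in c(-6, 0, 6)) {
    expect_true(all(diff(late_factor(tt, t_prime = tp)) >= 0))
    expect_true(all(diff(late_factor(tt, exponential = TRUE,
                                     t_prime = tp)) >= 0))
  }
  # timing shift displaces the onset
  expect_equal(late_factor(154, t_prime = 6), 0)
  expect_equal(late_factor(183 + 6, t_prime = 6), 0.1680)
})

test_that("EARLYGROWTH declines linearly after 189 h to a floor of zero", {
  expect_equal(earlygrowth_factor(150), 1)
  expect_equal(earlygrowth_factor(201), 1 - 0.0417 * 12)
  expect_equal(earlygrowth_factor(300), 0)
  expect_equal(earlygrowth_factor(195, t_prime = 6), 1)
})

test_that("polarity establishes proximodistally from the base", {
  cv <- build_initial_canvas(leaf_geometry(n_u = 10, n_v = 16))
  fx <- init_fixed_factors(cv)
  ps <- establish_polarity(cv, fx$proxorg)
  expect_equal(unname(ps$pol[cv$base_nodes]),
               rep(krn_params()$b_pol, length(cv$base_nodes)))
  # median polarity axis within a few degrees of the proximodistal axis
  dev <- abs(ps$angle * 180 / pi - 90)
  expect_lt(median(dev), 10)
})

test_that("PMF steady state matches the 1D diffusion-decay profile", {
  # near-1D rod: uniform width, source row near the base
  geom <- leaf_geometry(length = 2000, half_width_lamina = 50,
                        half_width_petiole = 50, half_width_tip = 50,
                        plb_frac = 0.1, n_u = 6, n_v = 100)
  cv <- build_initial_canvas(geom)
  p <- krn_params()
  pmf <- leafdyn:::init_pmf(cv, p)
  lambda <- sqrt(leafdyn:::pmf_diffusivity(p) / p$mu_pmf)
  mid <- cv$midline_nodes
  d <- dist_to_plb(cv, cv$param[mid, "v"])
  sel <- d > 0 & d < 800          # distal, away from the far boundary
  expect_lt(max(abs(pmf[mid][sel] / exp(-d[sel] / lambda) - 1)), 0.02)
  # Dirichlet condition holds exactly on the source band
  expect_true(all(pmf[cv$plb_nodes] == 1))
})

test_that("decay-only update follows the implicit-Euler scalar ODE", {
  cv <- build_initial_canvas(leaf_geometry(n_u = 6, n_v = 8))
  p <- krn_params(d_pmf = 0, pmf_dilute = FALSE)
  v0 <- rep(0.8, nrow(cv$nodes))
  out <- update_pmf(cv, v0, dt = 1, params = p)
  free <- setdiff(seq_len(nrow(cv$nodes)), cv$plb_nodes)
  expect_equal(out[free], rep(0.8 / (1 + p$mu_pmf), length(free)),
               tolerance = 1e-9)
})

test_that("PMFTK caps PMF at 0.295", {
  expect_equal(pmftk(c(0, 0.2, 0.295, 0.8)), c(0, 0.2, 0.295, 0.295))
})

test_that("specified growth reproduces the early-model formulas", {
  p <- krn_params()
  f1 <- list(pgrad = 1, lam = 0, mid = 0, pmftk = 0)
  vr <- model_variant("subepidermis_early")
  r <- specified_growth_rates(f1, late = 0, eg = 1, vr, p)
  expect_equal(r$k_par, 0.041)
  f2 <- list(pgrad = 0, lam = 1, mid = 0, pmftk = 0)
  r2 <- specified_growth_rates(f2, 0, 1, vr, p)
  expect_equal(r2$k_per, 0.0235)
  f3 <- list(pgrad = 0, lam = 1, mid = 1, pmftk = 0)
  r3 <- specified_growth_rates(f3, 0, 1, vr, p)
  expect_equal(r3$k_per, 0.0235 * 0.5)
  # LATE acts as printed: inhibition of k_par, promotion of k_per
  r4 <- specified_growth_rates(f1, late = 0.1, eg = 1, vr, p)
  expect_equal(r4$k_par, 0.041 / (1 + 2.2 * 0.1))
})

test_that("cell-size feedback and mutant scalings act as specified", {
  p <- krn_params()
  f <- list(pgrad = 1, lam = 1, mid = 0, pmftk = 0.2)
  vlim <- model_variant("limiting_cell_size")
  r_half <- specified_growth_rates(f, 0.1, 1, vlim, p,
                                   cell_area = 6000, midline = FALSE)
  r_full <- specified_growth_rates(f, 0.1, 1, vlim, p,
                                   cell_area = 4000, midline = FALSE)
  expect_equal(r_half$k_par / r_full$k_par, 0.5)
  expect_equal(r_half$k_per / r_full$k_per, 0.5)
  # k' scales every rate exactly
  vr1 <- model_variant("limit_free")
  vr2 <- model_variant("limit_free", k_prime = 1.05)
  a <- specified_growth_rates(f, 0.2, 0.7, vr1, p)
  b <- specified_growth_rates(f, 0.2, 0.7, vr2, p)
  expect_equal(b$k_par / a$k_par, 1.05)
  expect_equal(b$k_per / a$k_per, 1.05)
})
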
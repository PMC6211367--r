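# Shared simulation cache: several test files interrogate the same
# preset runs, so each configuration is run once per test session.
# Tests use a reduced problem size (coarser mesh and packing, 2-h step)
# except where a check is about the default-resolution model.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

coarse_geom <- function() leaf_geometry(n_u = 14, n_v = 24)

coarse_config <- function(variant, seed = 1, ...)
  leaf_config(variant, seed = seed, geom = coarse_geom(),
              n_cu = 5, n_cv = 11, dt = 2, ...)

coarse_sim <- function(variant, seed = 1, ...) {
  key <- paste(variant, seed, ..., sep = "|")
  cached(key, function()
    run_leaf_model(coarse_config(variant, seed = seed, ...)))
}

# time-averaged distal competence limit (um from the petiole-lamina
# boundary) over snapshots at t >= tmin
competence_limit <- function(sim, tmin = 124) {
  x <- vapply(sim$snapshots, function(s)
    c(s$t, if (any(s$competent)) max(s$dist_plb[s$competent]) else NA_real_),
    numeric(2))
  mean(x[2, x[1, ] >= tmin], na.rm = TRUE)
}

# mother areas at execution in the proximal 150 um of lamina
proximal_exec_areas <- function(sim) {
  ev <- sim$events
  ev$mother_area[ev$region == "lamina" & ev$dist_plb >= 0 &
                   ev$dist_plb < 150]
}

# simple convex test polygon helpers
unit_rect <- function(w, h) cbind(c(0, w, w, 0), c(0, 0, h, h))
regular_polygon <- function(n, r = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(th), r * sin(th))
}
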
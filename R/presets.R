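#' Simulation configuration
#'
#' Assembles a runnable model configuration: variant, geometry, network
#' parameters, division parameters, v-cell packing, time span and output
#' times.  Early-stage presets run 87-178 h; late-stage presets run
#' 87-412 h.  Snapshots default to the published output times of the
#' early models (115, 132, 140, 147, 156, 164, 178 h) plus every 12 h.
#'
#' @param variant a \code{\link{model_variant}} or a variant name
#' @param seed RNG seed recorded in the output
#' @param dt time step in hours
#' @param t_end end of the growth period (h); default by variant
#' @param out_times snapshot times (h)
#' @param geom a \code{\link{leaf_geometry}}
#' @param params a \code{\link{krn_params}}
#' @param divparams a \code{\link{division_params}} (default by layer)
#' @param n_cu,n_cv,jitter initial v-cell packing (see
#'   \code{\link{init_tissue}})
#' @param mid_half_width half-width (um) of the MID stripe / midline
#'   region
#' @param divisions logical; run the division engine
#' @param spaces logical; simulate intercellular spaces (default: only
#'   in the subepidermal variant)
#' @param isotropic logical; remove polarity (isotropic specified growth
#'   preserving the local areal rate), the topology control
#' @return list of class \code{"leaf_config"}
#' @export
leaf_config <- function(variant = "epidermis_early", seed = 1, dt = 1,
                        t_end = NULL, out_times = NULL,
                        geom = leaf_geometry(), params = krn_params(),
                        divparams = NULL, n_cu = 9, n_cv = 26,
                        jitter = 0.2, mid_half_width = 16,
                        divisions = TRUE, spaces = NULL,
                        isotropic = FALSE) {
  if (is.character(variant)) variant <- model_variant(variant)
  stopifnot(inherits(variant, "model_variant"))
  early <- variant$krn == "early"
  if (is.null(t_end)) t_end <- if (early) 178 else 412
  stopifnot(t_end > 87)
  if (is.null(out_times)) {
    out_times <- sort(unique(c(c(115, 132, 140, 147, 156, 164, 178),
                               seq(99, t_end, by = 12), t_end)))
    out_times <- out_times[out_times > 87 & out_times <= t_end]
  }
  if (is.null(divparams)) divparams <- division_params(variant$layer)
  if (is.null(spaces)) spaces <- variant$layer == "subepidermis"
  structure(list(variant = variant, seed = seed, dt = dt, t_start = 87,
                 t_end = t_end, out_times = out_times, geom = geom,
                 params = params, divparams = divparams,
                 n_cu = n_cu, n_cv = n_cv, jitter = jitter,
                 mid_half_width = mid_half_width, divisions = divisions,
                 spaces = spaces, isotropic = isotropic),
            class = "leaf_config")
}

# nodal field -> element means
field_on_elements <- function(canvas, field) {
  el <- canvas$elements
  (field[el[, 1]] + field[el[, 2]] + field[el[, 3]]) / 3
}

# nodal field interpolated at the tissue's vertex anchors
field_at_vertices <- function(tis, field) {
  el <- tis$cv$elements[tis$vt_elem, , drop = FALSE]
  b <- tis$vt_b
  b[, 1] * field[el[, 1]] + b[, 2] * field[el[, 2]] + b[, 3] * field[el[, 3]]
}

# mean of a per-vertex quantity over each living cell's cycle
cell_field_mean <- function(tis, vert_vals) {
  vapply(seq_along(tis$cells), function(i) {
    if (!tis$alive[i]) return(NA_real_)
    mean(vert_vals[tis$cells[[i]]])
  }, numeric(1))
}

# growth step with halving on element inversion
step_growth_adaptive <- function(canvas, spec, dt, depth = 0) {
  out <- tryCatch(step_growth(canvas, spec, dt), error = function(e) e)
  if (!inherits(out, "error")) return(out)
  if (depth >= 4) stop(out)
  half <- step_growth_adaptive(canvas, spec, dt / 2, depth + 1)
  step_growth_adaptive(half, spec, dt / 2, depth + 1)
}

#' Run a model preset
#'
#' Executes the full time loop: temporal factors (in physiological time
#' for the environment presets), PMF diffusion-decay on the growing
#' canvas, specified-growth evaluation, mechanics, advection of all
#' anchored quantities, competence and division, and intercellular
#' spaces.  Bit-reproducible given (config, seed).
#'
#' @param config a \code{\link{leaf_config}}
#' @return object of class \code{"leaf_sim"}: config, snapshot list,
#'   division-event table, and the final tissue state
#' @export
run_leaf_model <- function(config) {
  stopifnot(inherits(config, "leaf_config"))
  set.seed(config$seed)
  vr <- config$variant
  pars <- config$params
  dp <- config$divparams
  canvas <- build_initial_canvas(config$geom)
  fx <- init_fixed_factors(canvas, pars, config$mid_half_width)
  polset <- establish_polarity(canvas, fx$proxorg, pars)
  pol <- polset$pol
  pmf <- init_pmf(canvas, pars)
  tis <- init_tissue(canvas, vr, config$n_cu, config$n_cv, config$jitter,
                     config$mid_half_width)
  tis$target_eps <- pmax(stats::rnorm(length(tis$cells), 1, dp$sigma_frac), 0.3)
  tis$birth[] <- config$t_start

  abar_now <- function(t) {
    tau <- physiological_time(t, vr, config$t_start)
    pmf_v <- field_at_vertices(tis, pmf)
    pg_v <- field_at_vertices(tis, fx$pgrad)
    cm_pmf <- cell_field_mean(tis, pmf_v)
    cm_pg <- cell_field_mean(tis, pg_v)
    mean_target_area(cm_pmf, cm_pg, tis$region, dp, tau, vr$a_prime)
  }
  snapshot <- function(t) {
    areas <- cell_areas(tis)
    dpl <- midline_arclength(tis$cv)
    vpar <- cell_v_param(tis)
    alive <- which(tis$alive)
    list(t = t, nodes = tis$cv$nodes, vt_pos = tis$vt_pos,
         cells = tis$cells[alive], cell_idx = alive,
         lineage = tis$lineage[alive], parent = tis$parent[alive],
         birth = tis$birth[alive], region = tis$region[alive],
         layer = tis$layer[alive], competent = tis$competent[alive],
         area = areas[alive], dist_plb = dpl(vpar[alive]),
         spaces = tis$spaces, pmf = pmf,
         measure = measure_leaf(tis$cv))
  }

  update_cell_state <- function(t) {
    tau <- physiological_time(t, vr, config$t_start)
    late <- late_factor(tau, pars, vr$late_exponential, vr$t_prime)
    pmf_v <- field_at_vertices(tis, pmf)
    pg_v <- field_at_vertices(tis, fx$pgrad)
    cm_pmf <- cell_field_mean(tis, pmf_v)
    cm_pg <- cell_field_mean(tis, pg_v)
    tis$competent <- update_competence(cm_pmf, cm_pg, tis$region, late, dp) &
      tis$alive
    abar <- mean_target_area(cm_pmf, cm_pg, tis$region, dp, tau, vr$a_prime)
    tis$target <- tis$target_eps * abar
  }

  update_cell_state(config$t_start)
  snaps <- list()
  pending <- sort(config$out_times)
  t <- config$t_start
  mass_old <- fem_operators(canvas)$mass
  while (t < config$t_end - 1e-9) {
    dt <- min(config$dt, config$t_end - t)
    tau <- physiological_time(t, vr, config$t_start)
    late <- late_factor(tau, pars, vr$late_exponential, vr$t_prime)
    eg <- earlygrowth_factor(tau, pars, vr$t_prime)
    ef <- list(pgrad = field_on_elements(canvas, fx$pgrad),
               lam = field_on_elements(canvas, fx$lam),
               mid = field_on_elements(canvas, fx$mid),
               pmftk = field_on_elements(canvas, pmftk(pmf, pars)))
    if (vr$krn == "limiting_cell_size") {
      areas <- cell_areas(tis)
      ca <- areas[tis$elem_cell]
      ca[is.na(ca)] <- mean(areas, na.rm = TRUE)
      mdl <- tis$region[tis$elem_cell] == "midline"
      mdl[is.na(mdl)] <- FALSE
      rates <- specified_growth_rates(ef, late, eg, vr, pars, ca, mdl)
    } else {
      rates <- specified_growth_rates(ef, late, eg, vr, pars)
    }
    ang <- polarity_angles(canvas, pol)
    if (config$isotropic) {
      k_iso <- (sqrt((1 + rates$k_par * dt) * (1 + rates$k_per * dt)) - 1) / dt
      spec <- specified_growth_field(k_iso, k_iso, ang, nrow(canvas$elements))
    } else {
      spec <- specified_growth_field(rates$k_par, rates$k_per, ang,
                                     nrow(canvas$elements))
    }
    canvas <- step_growth_adaptive(canvas, spec, dt)
    tis$cv <- canvas
    pmf <- update_pmf(canvas, pmf, dt, pars, mass_old)
    mass_old <- fem_operators(canvas)$mass
    refresh_positions(tis)
    advance_spaces(tis, dt)
    t <- t + dt
    update_cell_state(t)
    if (config$divisions)
      attempt_divisions(tis, t, function(cen, region) {
        anch <- locate_points(canvas, rbind(cen))
        el <- canvas$elements[anch$elem, ]
        w <- anch$b[1, ]
        pmf_c <- sum(w * pmf[el]); pg_c <- sum(w * fx$pgrad[el])
        mean_target_area(pmf_c, pg_c, region, dp,
                         physiological_time(t, vr, config$t_start),
                         vr$a_prime)
      }, dp)
    if (config$spaces)
      manage_spaces(tis, t, dt)
    while (length(pending) && t >= pending[1] - 1e-9) {
      snaps[[length(snaps) + 1L]] <- snapshot(t)
      pending <- pending[-1]
    }
  }
  ev <- if (length(tis$events)) do.call(rbind, tis$events) else
    data.frame(time = numeric(0), mother_lineage = integer(0),
               daughter1 = integer(0), daughter2 = integer(0),
               mother_area = numeric(0), mother_birth = numeric(0),
               x = numeric(0), y = numeric(0), dist_plb = numeric(0),
               region = character(0), layer = character(0))
  structure(list(config = config, snapshots = snaps, events = ev,
                 tissue = tis, factors = fx, pol = pol, pmf = pmf),
            class = "leaf_sim")
}

#' Summarize a simulation
#'
#' @param object a \code{leaf_sim}
#' @param ... unused
#' @return data.frame with one row per snapshot: time, cell count, mean
#'   cell area (um^2), leaf area (mm^2), leaf width (mm), space count
#' @export
summary.leaf_sim <- function(object, ...) {
  do.call(rbind, lapply(object$snapshots, function(s) {
    data.frame(t = s$t, n_cells = length(s$cells),
               mean_cell_area = mean(s$area),
               leaf_area_mm2 = s$measure$area_mm2,
               width_mm = s$measure$width_mm,
               n_spaces = length(s$spaces))
  }))
}

#' @export
print.leaf_sim <- function(x, ...) {
  s <- utils::tail(summary(x), 1)
  cat("leaf_sim:", x$config$variant$name, "variant, seed",
      x$config$seed, "\n")
  cat(sprintf("  final t = %g h: %d cells, mean area %.1f um^2, leaf %.3f mm^2, width %.3f mm\n",
              s$t, s$n_cells, s$mean_cell_area, s$leaf_area_mm2, s$width_mm))
  cat("  divisions:", nrow(x$events), " spaces:", s$n_spaces, "\n")
  invisible(x)
}

#' Plot a simulation snapshot
#'
#' Draws the v-cell packing (and intercellular spaces) at a snapshot.
#'
#' @param x a \code{leaf_sim}
#' @param snapshot snapshot index (default: last)
#' @param col fill colour mapping: \code{"area"} or \code{"region"}
#' @param ... passed to \code{plot.default}
#' @export
plot.leaf_sim <- function(x, snapshot = length(x$snapshots),
                          col = c("area", "region"), ...) {
  col <- match.arg(col)
  s <- x$snapshots[[snapshot]]
  pos <- s$vt_pos
  graphics::plot(NA, xlim = range(pos[, 1]), ylim = range(pos[, 2]),
                 asp = 1, xlab = "x (um)", ylab = "y (um)",
                 main = sprintf("%s, t = %g h", x$config$variant$name, s$t),
                 ...)
  fill <- if (col == "area") {
    pal <- grDevices::hcl.colors(64, "YlGnBu", rev = TRUE)
    pal[cut(log(s$area), 64, labels = FALSE)]
  } else ifelse(s$region == "midline", "thistle", "palegreen3")
  for (i in seq_along(s$cells))
    graphics::polygon(pos[s$cells[[i]], 1], pos[s$cells[[i]], 2],
                      col = fill[i], border = "grey30", lwd = 0.3)
  for (w in s$spaces)
    graphics::polygon(pos[w, 1], pos[w, 2], col = "white", border = NA)
  invisible(x)
}

#' Mutant comparison matrix
#'
#' Runs a late-stage base preset and its six mutants (division-threshold
#' a' = +/-85 um^2, growth-rate k' = 0.95/1.05, timing t' = -/+6 h) with
#' matched seeds and returns final-state comparisons.
#'
#' @param base \code{"limit_free"} or \code{"limiting_cell_size"}
#' @param seed shared RNG seed
#' @param ... further arguments to \code{\link{leaf_config}} (e.g.
#'   coarse mesh settings)
#' @return data.frame of final cell count, mean cell area and leaf area
#'   for the base and each mutant, with percent changes vs base
#' @export
mutant_matrix <- function(base = c("limit_free", "limiting_cell_size"),
                          seed = 1, ...) {
  base <- match.arg(base)
  muts <- list(base = list(),
               a_plus = list(a_prime = 85), a_minus = list(a_prime = -85),
               k_plus = list(k_prime = 1.05), k_minus = list(k_prime = 0.95),
               t_plus = list(t_prime = 6), t_minus = list(t_prime = -6))
  rows <- lapply(names(muts), function(nm) {
    vr <- do.call(model_variant, c(list(name = base), muts[[nm]]))
    sim <- run_leaf_model(leaf_config(variant = vr, seed = seed, ...))
    s <- utils::tail(summary(sim), 1)
    data.frame(model = nm, n_cells = s$n_cells,
               mean_cell_area = s$mean_cell_area,
               leaf_area_mm2 = s$leaf_area_mm2, width_mm = s$width_mm)
  })
  out <- do.call(rbind, rows)
  b <- out[out$model == "base", ]
  out$d_cells_pct <- 100 * (out$n_cells / b$n_cells - 1)
  out$d_area_pct <- 100 * (out$mean_cell_area / b$mean_cell_area - 1)
  out$d_leaf_pct <- 100 * (out$leaf_area_mm2 / b$leaf_area_mm2 - 1)
  out
}
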
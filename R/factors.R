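#' Growth-regulatory-network parameters
#'
#' Defaults are the published model parameters: polarity (b_pol, mu_pol),
#' growth (b_pgrad, g_late, p_pgrad, p_lam, p_late, h_late, h_mid) and
#' mobile-factor (mu_pmf, d_pmf, p_pmf) coefficients, the PMFTK cap, the
#' variant-specific inhibition coefficients of the late-stage models, and
#' the EARLYGROWTH decline slope.  \code{d_pmf} is in mm^2/h;
#' \code{pmf_length_scale} is a dimensionless calibration on the PMF
#' diffusion length (see vignette) fixed so that the PMF = 0.184 contour
#' of the running early model sits near 400 um from the petiole-lamina
#' boundary.
#'
#' @param ... named overrides of any default
#' @return list of class \code{"krn_params"}
#' @export
krn_params <- function(...) {
  p <- list(
    b_pol = 0.1, mu_pol = 0.1, d_pol = 9000,      # d_pol um^2/h (calibration)
    b_pgrad = 0.195, g_late = 0.0048,
    p_pgrad = 0.041, p_lam = 0.0235, p_late = 0.7,
    h_late = 2.2, h_mid = 1.0,
    mu_pmf = 0.3, d_pmf = 0.01, p_pmf = 0.9,
    pmf_cap = 0.295, pmf_length_scale = 1.72, pmf_dilute = TRUE,
    late_onset = 148, late_exp_break = 189,
    earlygrowth_slope = 0.0417, earlygrowth_break = 189,
    # late-stage variant inhibition coefficients
    h_eg_par_mature = 0.24, h_eg_per_mature = 2.8,
    h_latesoft_limitfree = 1.5, h_lam_limitfree = 2,
    h_pgrad_limitfree = 4, h_eg_per_limitfree = 1.2,
    # limiting-cell-size thresholds (um^2)
    a1_lamina = 4000, a2_lamina = 8000,
    a1_midline = 18000, a2_midline = 20000
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown krn parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  structure(p, class = "krn_params")
}

#' Promotion and inhibition response functions
#'
#' \code{pro(p, i) = 1 + p * i} and \code{inh(h, i) = 1 / (1 + h * i)},
#' elementwise over factor fields.
#'
#' @param p,h nonnegative coefficient
#' @param i factor level(s)
#' @return multiplier(s)
#' @export
pro <- function(p, i) {
  stopifnot(all(p >= 0))
  1 + p * i
}

#' @rdname pro
#' @export
inh <- function(h, i) {
  stopifnot(all(h >= 0))
  1 / (1 + h * i)
}

#' Temporal factor LATE
#'
#' Zero before onset (148 h), then rising linearly with slope
#' \code{g_late}; in the late-stage (mature-family) models the rise
#' becomes exponential, A e^{B t} with B = 1/(189-148) and A chosen for
#' continuity at 189 h.  A timing-mutant shift \code{t_prime} displaces
#' the whole schedule in time.
#'
#' @param t time(s) in hours after initiation
#' @param params a \code{\link{krn_params}}
#' @param exponential logical; use the late-stage exponential branch
#' @param t_prime timing shift in hours (positive = later)
#' @return LATE level(s)
#' @export
late_factor <- function(t, params = krn_params(), exponential = FALSE,
                        t_prime = 0) {
  ts <- t - t_prime
  on <- params$late_onset; br <- params$late_exp_break
  g <- params$g_late
  out <- ifelse(ts < on, 0, g * (ts - on))
  if (exponential) {
    B <- 1 / (br - on)
    A <- g * (br - on) * exp(-B * br)
    out <- ifelse(ts >= br, A * exp(B * ts), out)
  }
  out
}

#' Temporal factor EARLYGROWTH
#'
#' One until 189 h, then declining linearly at 0.0417 per hour to a floor
#' of zero.  Shifted in time by \code{t_prime} in timing mutants.
#'
#' @inheritParams late_factor
#' @return EARLYGROWTH level(s) in [0, 1]
#' @export
earlygrowth_factor <- function(t, params = krn_params(), t_prime = 0) {
  ts <- t - t_prime
  br <- params$earlygrowth_break
  pmin(1, pmax(0, 1 - params$earlygrowth_slope * (ts - br) * (ts >= br)))
}

#' Initial tissue-fixed factor fields
#'
#' PGRAD declines linearly from 1 at the base to \code{b_pgrad} at the
#' tip; LAM rises sigmoidally across the petiole-lamina boundary; MID is
#' a smooth stripe about the midline; PROXORG marks the base row.  All
#' values are attached to mesh nodes and deform with the canvas (no
#' diffusion).
#'
#' @param canvas a \code{leaf_canvas}
#' @param params a \code{\link{krn_params}}
#' @param mid_half_width half-width of the MID stripe (um) in the initial
#'   configuration
#' @param lam_sharpness width (in v units) of the LAM transition
#' @return list of per-node fields (pgrad, lam, mid, proxorg)
#' @export
init_fixed_factors <- function(canvas, params = krn_params(),
                               mid_half_width = 16, lam_sharpness = 0.04) {
  v <- canvas$param[, "v"]
  x <- canvas$nodes0[, 1]
  pgrad <- 1 - (1 - params$b_pgrad) * v
  lam <- stats::plogis((v - canvas$geom$plb_frac) / lam_sharpness)
  mid <- exp(-(abs(x) / mid_half_width)^4)
  proxorg <- as.numeric(v == 0)
  list(pgrad = pgrad, lam = lam, mid = mid, proxorg = proxorg)
}

#' Establish the polarity field
#'
#' POL is clamped to \code{b_pol} where PROXORG > 0 (the canvas base) and
#' diffuses with decay for 20 one-hour setup steps before growth starts.
#' The per-element polarity axis is the direction of \code{-grad(POL)}
#' (pointing distally, down the gradient); thereafter POL is frozen to
#' the nodes and the axis is re-derived from the deforming geometry, so
#' polarity deforms with the canvas.
#'
#' @param canvas a \code{leaf_canvas}
#' @param proxorg per-node PROXORG field
#' @param params a \code{\link{krn_params}}
#' @param n_setup_steps number of setup diffusion steps (default 20)
#' @return list with per-node \code{pol} and per-element \code{angle}
#' @export
establish_polarity <- function(canvas, proxorg, params = krn_params(),
                               n_setup_steps = 20) {
  src <- which(proxorg > 0)
  ops <- fem_operators(canvas)
  pol <- numeric(nrow(canvas$nodes))
  for (s in seq_len(n_setup_steps))
    pol <- diffusion_step(canvas, pol, params$d_pol, params$mu_pol, 1,
                          src, params$b_pol, ops)
  list(pol = pol, angle = polarity_angles(canvas, pol))
}

#' Per-element polarity angles from a POL field
#'
#' Angle of \code{-grad(POL)} per element; elements with a vanishing
#' gradient inherit the angle of the nearest defined neighbour.
#'
#' @param canvas a \code{leaf_canvas}
#' @param pol per-node POL values
#' @return angles in radians, one per element
#' @export
polarity_angles <- function(canvas, pol) {
  el <- canvas$elements
  G <- element_shape_inverse(canvas)
  f1 <- pol[el[, 1]] - pol[el[, 3]]
  f2 <- pol[el[, 2]] - pol[el[, 3]]
  gx <- G$g11 * f1 + G$g21 * f2
  gy <- G$g12 * f1 + G$g22 * f2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(-gy, -gx)
  bad <- mag < 1e-12 | !is.finite(ang)
  if (any(bad)) {
    if (all(bad)) stop("POL gradient vanishes everywhere; polarity undefined")
    # inherit from nearest defined element centroid
    cen <- element_centroids(canvas)
    good <- which(!bad)
    for (e in which(bad)) {
      d2 <- (cen[good, 1] - cen[e, 1])^2 + (cen[good, 2] - cen[e, 2])^2
      ang[e] <- ang[good[which.min(d2)]]
    }
  }
  ang
}

#' Advance the PMF field by one step
#'
#' PMF is held at 1 on the anchored petiole-lamina boundary node row and
#' diffuses with decay over the current (growing) mesh.  By default the
#' concentration dilutes with growth (factor amounts are conserved
#' through the deformation via the lumped mass matrix, then the
#' diffusion-decay step is taken on the new geometry).
#'
#' @param canvas canvas after the growth step
#' @param pmf per-node PMF before the step
#' @param dt time step (h)
#' @param params a \code{\link{krn_params}}
#' @param mass_old lumped mass vector of the pre-growth mesh (for
#'   dilution); NULL disables dilution for this step
#' @return updated per-node PMF
#' @export
update_pmf <- function(canvas, pmf, dt, params = krn_params(),
                       mass_old = NULL) {
  ops <- fem_operators(canvas)
  if (isTRUE(params$pmf_dilute) && !is.null(mass_old))
    pmf <- pmf * mass_old / ops$mass
  D <- pmf_diffusivity(params)
  out <- diffusion_step(canvas, pmf, D, params$mu_pmf, dt,
                        canvas$plb_nodes, 1, ops)
  pmin(pmax(out, 0), 1)
}

# effective PMF diffusivity in um^2/h: d_pmf [mm^2/h] with the
# length-scale calibration applied
pmf_diffusivity <- function(params)
  params$d_pmf * 1e6 * params$pmf_length_scale^2

# steady-state PMF on the current mesh (used for initialization)
init_pmf <- function(canvas, params = krn_params()) {
  out <- diffusion_steady(canvas, pmf_diffusivity(params), params$mu_pmf,
                          canvas$plb_nodes, 1)
  pmin(pmax(out, 0), 1)
}

#' Capped PMF (PMFTK)
#'
#' PMFTK equals PMF except where PMF >= 0.295, where it is capped.
#' @param pmf PMF level(s)
#' @param params a \code{\link{krn_params}}
#' @return capped values
#' @export
pmftk <- function(pmf, params = krn_params()) pmin(pmf, params$pmf_cap)
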
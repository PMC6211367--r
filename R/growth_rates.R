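#' Model variants
#'
#' A variant names the growth-regulatory-network wiring and division
#' rules of one published model: the two early-stage models
#' (\code{"subepidermis_early"}, \code{"epidermis_early"}), the
#' late-stage epidermal models (\code{"mature"}, \code{"limit_free"},
#' \code{"limiting_cell_size"}), and the environment presets
#' (\code{"plate"}: physiological ratio 0.55 with global growth scale
#' 0.6; \code{"chamber_tuned"}: physiological ratio 0.75), both built on
#' the mature model.
#'
#' @param name base variant name
#' @param a_prime division-threshold mutant offset added to the lamina
#'   mean target area (um^2)
#' @param k_prime global scale on both specified growth rates
#' @param t_prime timing shift of LATE and EARLYGROWTH (h)
#' @return list of class \code{"model_variant"}
#' @export
model_variant <- function(name = c("subepidermis_early", "epidermis_early",
                                   "mature", "limit_free",
                                   "limiting_cell_size", "plate",
                                   "chamber_tuned"),
                          a_prime = 0, k_prime = 1, t_prime = 0) {
  name <- match.arg(name)
  phys_ratio <- switch(name, plate = 0.55, chamber_tuned = 0.75, 1)
  if (name == "plate") k_prime <- k_prime * 0.6
  krn <- switch(name,
                subepidermis_early = , epidermis_early = "early",
                limit_free = "limit_free",
                limiting_cell_size = "limiting_cell_size",
                "mature")
  layer <- if (name == "subepidermis_early") "subepidermis" else "epidermis"
  structure(list(name = name, krn = krn, layer = layer,
                 a_prime = a_prime, k_prime = k_prime, t_prime = t_prime,
                 phys_ratio = phys_ratio,
                 late_exponential = krn != "early"),
            class = "model_variant")
}

#' Evaluate specified growth rates
#'
#' Evaluates the product-of-factors growth formulas of the active
#' variant.  Inputs are factor levels per evaluation point (typically
#' element means of the nodal fields); \code{late} and \code{eg}
#' (EARLYGROWTH) are scalars for the evaluation time.  For the
#' limiting-cell-size variant, \code{cell_area} (um^2 of the v-cell
#' covering each point) and \code{midline} (logical region flag) supply
#' the size-feedback factor
#' \code{omega = clamp((a2 - ca) / (a2 - a1), 0, 1)}.
#'
#' Growth-rate mutants scale both rates by \code{k_prime}; environment
#' presets additionally scale by the physiological ratio (growth per
#' actual hour when rates are set in physiological time).
#'
#' @param fields list with per-point \code{pgrad}, \code{lam},
#'   \code{mid}, \code{pmftk}
#' @param late,eg temporal factor levels (evaluated in physiological
#'   time by the caller)
#' @param variant a \code{\link{model_variant}}
#' @param params a \code{\link{krn_params}}
#' @param cell_area per-point covering v-cell area (limiting variant)
#' @param midline per-point logical, TRUE in the midline region
#' @return list with \code{k_par} and \code{k_per} (per hour)
#' @export
specified_growth_rates <- function(fields, late, eg, variant,
                                   params = krn_params(),
                                   cell_area = NULL, midline = NULL) {
  pg <- fields$pgrad; lam <- fields$lam; mid <- fields$mid
  tk <- fields$pmftk
  kp <- switch(variant$krn,
    early = params$p_pgrad * pg * inh(params$h_late, late),
    mature = params$p_pgrad * pg * inh(params$h_late, late) *
      inh(params$h_eg_par_mature, late * (1 - eg)),
    limit_free = params$p_pgrad * pg *
      inh(params$h_late, late * inh(params$h_latesoft_limitfree, 1 - eg)) *
      inh(params$h_lam_limitfree, (1 - lam) * (1 - eg)) *
      inh(params$h_pgrad_limitfree, (1 - pg) * (1 - eg)),
    limiting_cell_size = params$p_pgrad * pg * inh(params$h_late, late) *
      inh(params$h_eg_par_mature, late * (1 - eg))
  )
  kq <- switch(variant$krn,
    early = params$p_lam * lam * pro(params$p_late, late) *
      inh(params$h_mid, mid) * pro(params$p_pmf, tk),
    mature = params$p_lam * lam * inh(params$h_mid, mid) *
      pro(params$p_pmf, tk) * pro(params$p_late, late * eg) *
      inh(params$h_eg_per_mature, late * (1 - eg)),
    limit_free = params$p_lam * lam * inh(params$h_mid, mid) *
      pro(params$p_pmf, tk) * pro(params$p_late, late * eg) *
      inh(params$h_eg_per_limitfree, late * (1 - eg)) *
      inh(params$h_pgrad_limitfree, (1 - pg) * (1 - eg)),
    limiting_cell_size = params$p_lam * lam * inh(params$h_mid, mid) *
      pro(params$p_pmf, tk) * pro(params$p_late, late * eg) *
      inh(params$h_eg_per_mature, late * (1 - eg))
  )
  if (variant$krn == "limiting_cell_size") {
    if (is.null(cell_area) || is.null(midline))
      stop("limiting_cell_size requires cell_area and midline")
    a1 <- ifelse(midline, params$a1_midline, params$a1_lamina)
    a2 <- ifelse(midline, params$a2_midline, params$a2_lamina)
    omega <- pmin(pmax((a2 - cell_area) / (a2 - a1), 0), 1)
    kp <- kp * omega
    kq <- kq * omega
  }
  scale <- variant$k_prime * variant$phys_ratio
  list(k_par = scale * kp, k_per = scale * kq)
}

# physiological time for temporal-factor evaluation: a constant fraction
# of the duration since simulation start (87 h); identity when the
# physiological ratio is 1
physiological_time <- function(t, variant, t_start = 87)
  variant$phys_ratio * (t - t_start) + t_start
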
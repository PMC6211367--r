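#' Division-rule parameters
#'
#' Competence thresholds and target-area parameters of the stochastic
#' division engine.  Defaults are the published subepidermal/epidermal
#' values: competence requires PMF >= \code{pmf_min} (0.184
#' subepidermis, 0.295 epidermis), plus PGRAD >= 0.628 in the epidermis;
#' competence is switched off everywhere once LATE reaches 0.1680
#' (0.0768 in the epidermal midline).  The mean target area is
#' \code{a_min} = 150 before 114 h; afterwards it interpolates from
#' \code{a_min} to \code{a_max} = 300 um^2 as PMF falls from
#' \code{pmf_max} = 0.51 to \code{pmf_min} in the lamina, and uses
#' \code{a_mid} = 500 um^2 in the midline (times 1.5 * PGRAD in the
#' subepidermis).  Sampled targets are normal with sd = 0.2 * mean.
#'
#' @param layer \code{"subepidermis"} or \code{"epidermis"}
#' @param ... named overrides
#' @return list of class \code{"division_params"}
#' @export
division_params <- function(layer = c("subepidermis", "epidermis"), ...) {
  layer <- match.arg(layer)
  p <- list(
    a_min = 150, a_max = 300, a_mid = 500,
    pmf_max = 0.51,
    pmf_min = if (layer == "epidermis") 0.295 else 0.184,
    pgrad_gate = if (layer == "epidermis") 0.628 else NA_real_,
    late_off = 0.1680,
    late_off_midline = if (layer == "epidermis") 0.0768 else 0.1680,
    sigma_frac = 0.2, onset_t = 114,
    noise_frac = 0.25, shorten_frac = 0.05,
    min_divisible_area = 4, layer = layer
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown division parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(p$a_min <= p$a_max, p$pmf_min < p$pmf_max)
  structure(p, class = "division_params")
}

#' Mean division target area
#'
#' @param pmf,pgrad factor levels at the cell (vectors allowed)
#' @param region \code{"lamina"} or \code{"midline"} per cell
#' @param dp a \code{\link{division_params}}
#' @param t time (h); before \code{onset_t} the mean target is
#'   \code{a_min} everywhere
#' @param a_prime division-threshold mutant offset (applied to the
#'   lamina target for t >= onset)
#' @return mean target area(s) in um^2
#' @export
mean_target_area <- function(pmf, pgrad, region, dp, t, a_prime = 0) {
  n <- max(length(pmf), length(region))
  pmf <- rep_len(pmf, n); pgrad <- rep_len(pgrad, n)
  region <- rep_len(region, n)
  if (t < dp$onset_t) return(rep(dp$a_min, n))
  alpha <- pmin(pmax((dp$pmf_max - pmf) / (dp$pmf_max - dp$pmf_min), 0), 1)
  lam <- dp$a_min * (1 - alpha) + dp$a_max * alpha + a_prime
  mid <- if (dp$layer == "subepidermis") 1.5 * dp$a_mid * pgrad
         else rep(dp$a_mid, n)
  ifelse(region == "midline", mid, lam)
}

#' Sample a division target area
#'
#' Normal with mean \code{abar} and sd \code{sigma_frac * abar},
#' truncated below at \code{0.3 * abar} (a 3.5-sigma event at the
#' default sd, preserving the stated moments to better than 0.1\%).
#'
#' @param abar mean target area(s)
#' @param sigma_frac relative standard deviation
#' @return sampled target(s)
#' @export
sample_target <- function(abar, sigma_frac = 0.2) {
  if (sigma_frac == 0) return(abar)
  a <- stats::rnorm(length(abar), abar, sigma_frac * abar)
  pmax(a, 0.3 * abar)
}

#' Update competence (CDIV) flags
#'
#' A cell is competent iff PMF at its centroid is at least
#' \code{pmf_min}, PGRAD passes the epidermal gate (if any), and LATE is
#' below the arrest threshold (with the reduced midline threshold in the
#' epidermis).
#'
#' @param pmf,pgrad factor levels at the cell centroids
#' @param region region labels per cell
#' @param late current LATE level (physiological time)
#' @param dp a \code{\link{division_params}}
#' @return logical vector of competence flags
#' @export
update_competence <- function(pmf, pgrad, region, late, dp) {
  ok <- pmf >= dp$pmf_min
  if (!is.na(dp$pgrad_gate)) ok <- ok & (pgrad >= dp$pgrad_gate)
  off <- ifelse(region == "midline", dp$late_off_midline, dp$late_off)
  # arrest applies once LATE reaches the threshold (tolerant comparison:
  # the threshold values are exact decimals of the LATE schedule)
  ok & (late < off - 1e-9)
}

# ---- Errera geometry ---------------------------------------------------

# chord of polygon P through point q with direction d: returns the two
# parameters (t-, t+) bracketing q and the edge indices hit, or NULL
polygon_chord <- function(P, q, d) {
  n <- nrow(P)
  i2 <- c(2:n, 1)
  ex <- P[i2, 1] - P[, 1]; ey <- P[i2, 2] - P[, 2]
  rx <- P[, 1] - q[1]; ry <- P[, 2] - q[2]
  den <- d[1] * ey - d[2] * ex
  s <- (rx * d[2] - ry * d[1]) / den      # along-edge parameter
  tt <- (rx * ey - ry * ex) / den         # along-chord parameter
  ok <- is.finite(s) & s >= 0 & s < 1 & is.finite(tt)
  if (!any(ok)) return(NULL)
  tneg <- tt[ok][tt[ok] <= 0]
  tpos <- tt[ok][tt[ok] > 0]
  if (!length(tneg) || !length(tpos)) return(NULL)
  tm <- max(tneg); tp <- min(tpos)
  em <- which(ok)[which(tt[ok] == tm)[1]]
  ep <- which(ok)[which(tt[ok] == tp)[1]]
  if (em == ep) return(NULL)
  list(tm = tm, tp = tp, len = tp - tm, e_m = em, e_p = ep,
       s_m = s[em], s_p = s[ep])
}

# shortest wall through the polygon centroid: coarse angular scan plus
# golden-section refinement; ties broken by the smallest scan angle
shortest_wall <- function(P, n_scan = 180) {
  cen <- polygon_centroid(P)
  thetas <- seq(0, pi, length.out = n_scan + 1)[-(n_scan + 1)]
  lens <- vapply(thetas, function(th) {
    ch <- polygon_chord(P, cen, c(cos(th), sin(th)))
    if (is.null(ch)) Inf else ch$len
  }, numeric(1))
  k <- which.min(lens)
  lo <- thetas[k] - pi / n_scan; hi <- thetas[k] + pi / n_scan
  f <- function(th) {
    ch <- polygon_chord(P, cen, c(cos(th), sin(th)))
    if (is.null(ch)) 1e12 else ch$len   # finite sentinel for optimize()
  }
  opt <- stats::optimize(f, c(lo, hi))
  th <- opt$minimum
  ch <- polygon_chord(P, cen, c(cos(th), sin(th)))
  if (is.null(ch)) { th <- thetas[k]; ch <- polygon_chord(P, cen, c(cos(th), sin(th))) }
  list(theta = th, centre = cen, chord = ch)
}

#' Divide a polygon by the noisy shortest-wall rule
#'
#' The nominal wall is the global minimum-length chord through the area
#' centroid.  The actual wall is parallel to it, through the midpoint
#' displaced by a vector drawn uniformly from a disc of radius
#' \code{noise_frac} times the nominal wall length; the new wall is
#' shortened slightly by pulling its endpoints along the intersected
#' edges.  Draws from the session RNG.
#'
#' @param P polygon vertex matrix (counterclockwise)
#' @param noise_frac disc radius as a fraction of nominal wall length
#' @param shorten_frac endpoint pull-in as a fraction of wall length
#' @param max_tries resample attempts before falling back to the
#'   nominal wall
#' @return list with endpoint coordinates, their edge indices and edge
#'   parameters, or NULL if the polygon cannot be divided
#' @export
errera_wall <- function(P, noise_frac = 0.25, shorten_frac = 0.05,
                        max_tries = 10) {
  sw <- shortest_wall(P)
  ch0 <- sw$chord
  if (is.null(ch0)) return(NULL)
  d <- c(cos(sw$theta), sin(sw$theta))
  mid <- sw$centre + d * (ch0$tm + ch0$tp) / 2
  L0 <- ch0$len
  pick <- NULL
  for (try in seq_len(max_tries)) {
    if (try == max_tries || noise_frac == 0) { q <- mid }
    else {
      r <- noise_frac * L0 * sqrt(stats::runif(1))
      phi <- stats::runif(1, 0, 2 * pi)
      q <- mid + r * c(cos(phi), sin(phi))
    }
    ch <- polygon_chord(P, q, d)
    if (is.null(ch) || ch$e_m == ch$e_p) next
    pick <- list(q = q, ch = ch)
    break
  }
  if (is.null(pick)) return(NULL)
  ch <- pick$ch; q <- pick$q
  n <- nrow(P); i2 <- c(2:n, 1)
  wall_endpoint <- function(e, s) P[e, ] + s * (P[i2[e], ] - P[e, ])
  p_m <- q + ch$tm * d
  p_p <- q + ch$tp * d
  Lw <- sqrt(sum((p_p - p_m)^2))
  # shorten: pull each endpoint along its edge toward the other endpoint
  adjust <- function(e, s, here, other) {
    ev <- P[i2[e], ] - P[e, ]
    elen <- sqrt(sum(ev^2))
    step <- shorten_frac * Lw / elen
    dir <- sign(sum(ev * (other - here)))
    if (dir == 0) dir <- 1
    min(max(s + dir * step, 0.02), 0.98)
  }
  s_m <- adjust(ch$e_m, ch$s_m, p_m, p_p)
  s_p <- adjust(ch$e_p, ch$s_p, p_p, p_m)
  list(e_m = ch$e_m, s_m = s_m, p_m = wall_endpoint(ch$e_m, s_m),
       e_p = ch$e_p, s_p = s_p, p_p = wall_endpoint(ch$e_p, s_p),
       theta = sw$theta)
}

# split cycle positions 1..n at edges e1 < e2 with new vertex ids w1 (on
# edge e1) and w2 (on edge e2); returns the two daughter id cycles
split_cycle <- function(ids, e1, w1, e2, w2) {
  n <- length(ids)
  if (e1 > e2) { tmp <- e1; e1 <- e2; e2 <- tmp; tmp <- w1; w1 <- w2; w2 <- tmp }
  d1 <- c(w1, ids[(e1 + 1):e2], w2)
  d2 <- c(w2, ids[c(if (e2 < n) (e2 + 1):n else integer(0), 1:e1)], w1)
  list(d1, d2)
}

# insert vertex w between adjacent vertices a, b in every incident cycle
# (except `exclude`, used for the dividing mother whose cycle is split
# separately)
insert_on_edge <- function(tis, a, b, w, exclude = NULL) {
  owners <- intersect(tis$vert_inc[[a]], tis$vert_inc[[b]])
  if (!is.null(exclude)) owners <- setdiff(owners, exclude)
  for (ow in owners) {
    cyc <- if (ow > 0) tis$cells[[ow]] else tis$spaces[[-ow]]
    n <- length(cyc)
    ia <- match(a, cyc); ib <- match(b, cyc)
    if (is.na(ia) || is.na(ib)) next
    if ((ia %% n) + 1L == ib) pos <- ia
    else if ((ib %% n) + 1L == ia) pos <- ib
    else next
    cyc <- append(cyc, w, after = pos)
    if (ow > 0) tis$cells[[ow]] <- cyc else tis$spaces[[-ow]] <- cyc
    add_incidence(tis, w, ow)
  }
  invisible(NULL)
}

# divide one cell; returns the two daughter cell indices or NULL
divide_cell <- function(tis, cid, t, abar_fun, dp) {
  ids <- tis$cells[[cid]]
  P <- tis$vt_pos[ids, , drop = FALSE]
  if (polygon_area(P) < dp$min_divisible_area) return(NULL)
  wl <- errera_wall(P, dp$noise_frac, dp$shorten_frac)
  if (is.null(wl)) return(NULL)
  n <- length(ids)
  i2 <- c(2:n, 1)
  anch <- if (!is.null(tis$cv)) locate_points(tis$cv, rbind(wl$p_m, wl$p_p))
          else list(elem = c(NA_integer_, NA_integer_), b = matrix(NA_real_, 2, 3))
  # boundary flag: the cut edge lies on the outline iff it has a single
  # incident polygon
  bnd_m <- length(intersect(tis$vert_inc[[ids[wl$e_m]]],
                            tis$vert_inc[[ids[i2[wl$e_m]]]])) <= 1
  bnd_p <- length(intersect(tis$vert_inc[[ids[wl$e_p]]],
                            tis$vert_inc[[ids[i2[wl$e_p]]]])) <= 1
  w_m <- add_vertices(tis, list(elem = anch$elem[1], b = anch$b[1, , drop = FALSE]),
                      boundary = bnd_m)
  w_p <- add_vertices(tis, list(elem = anch$elem[2], b = anch$b[2, , drop = FALSE]),
                      boundary = bnd_p)
  tis$vt_pos <- rbind(tis$vt_pos, rbind(wl$p_m, wl$p_p))
  # insert into neighbours before splitting the mother
  insert_on_edge(tis, ids[wl$e_m], ids[i2[wl$e_m]], w_m, exclude = cid)
  insert_on_edge(tis, ids[wl$e_p], ids[i2[wl$e_p]], w_p, exclude = cid)
  dd <- split_cycle(ids, wl$e_m, w_m, wl$e_p, w_p)
  # retire mother, create daughters
  drop_incidence(tis, ids, cid)
  tis$alive[cid] <- FALSE
  out <- integer(2)
  for (k in 1:2) {
    did <- length(tis$cells) + 1L
    tis$cells[[did]] <- dd[[k]]
    tis$alive[did] <- TRUE
    tis$region[did] <- tis$region[cid]
    tis$layer[did] <- tis$layer[cid]
    tis$lineage[did] <- tis$next_lineage
    tis$next_lineage <- tis$next_lineage + 1L
    tis$parent[did] <- tis$lineage[cid]
    tis$birth[did] <- t
    tis$competent[did] <- tis$competent[cid]
    add_incidence(tis, dd[[k]], did)
    out[k] <- did
  }
  # fresh targets: the relative threshold deviation is drawn once at
  # birth (immutable); the mean target area is evaluated at the local
  # factor levels
  for (did in out) {
    cen <- polygon_centroid(tis$vt_pos[tis$cells[[did]], , drop = FALSE])
    eps <- if (dp$sigma_frac > 0)
      max(stats::rnorm(1, 1, dp$sigma_frac), 0.3) else 1
    if (!is.null(tis$target_eps)) tis$target_eps[did] <- eps
    tis$target[did] <- eps * abar_fun(cen, tis$region[did])
  }
  # reassign covered elements by wall side
  mine <- which(tis$elem_cell == cid)
  if (length(mine)) {
    ec <- element_centroids(tis$cv)[mine, , drop = FALSE]
    wv <- wl$p_p - wl$p_m
    side <- (ec[, 1] - wl$p_m[1]) * wv[2] - (ec[, 2] - wl$p_m[2]) * wv[1]
    # daughter 1 contains the polygon arc after e_m: decide by centroid side
    c1 <- polygon_centroid(tis$vt_pos[tis$cells[[out[1]]], , drop = FALSE])
    s1 <- (c1[1] - wl$p_m[1]) * wv[2] - (c1[2] - wl$p_m[2]) * wv[1]
    tis$elem_cell[mine] <- ifelse(sign(side) == sign(s1), out[1], out[2])
  }
  out
}

# attempt divisions for all competent cells above threshold; logs events
attempt_divisions <- function(tis, t, abar_fun, dp) {
  areas <- cell_areas(tis)
  ready <- which(tis$alive & tis$competent & !is.na(tis$target) &
                   areas >= tis$target)
  has_cv <- !is.null(tis$cv)
  vpar <- if (length(ready) && has_cv) cell_v_param(tis) else NULL
  dpl <- if (length(ready) && has_cv) midline_arclength(tis$cv) else
    function(v) NA_real_
  for (cid in ready) {
    cen <- polygon_centroid(tis$vt_pos[tis$cells[[cid]], , drop = FALSE])
    res <- divide_cell(tis, cid, t, abar_fun, dp)
    if (is.null(res)) next
    tis$events[[length(tis$events) + 1L]] <- data.frame(
      time = t, mother_lineage = tis$lineage[cid],
      daughter1 = tis$lineage[res[1]], daughter2 = tis$lineage[res[2]],
      mother_area = areas[cid], mother_birth = tis$birth[cid],
      x = cen[1], y = cen[2],
      dist_plb = if (has_cv) dpl(vpar[cid]) else NA_real_,
      region = tis$region[cid], layer = tis$layer[cid])
  }
  invisible(tis)
}
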
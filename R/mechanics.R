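# Growth mechanics: per-element prescribed deformation reconciled by a
# least-squares elastic-mismatch relaxation.
#
# Each element carries a target deformation gradient
#   F_t = R(theta) diag(1 + k_par dt, 1 + k_per dt) R(-theta)
# (stretch along/perpendicular to its polarity axis).  New node positions
# minimize sum_e A_e ||F_e(x) - F_t,e||_F^2, where F_e is the realized
# deformation gradient of element e (linear in the new positions).  The
# rows of F decouple, so the x and y coordinates solve two sparse SPD
# systems sharing one Cholesky factor.  When the specified growth is
# spatially uniform the residual is exactly zero: realized = specified.

# per-element inverse edge matrices G = S^{-1} with S = [p1-p3, p2-p3],
# returned as four numeric vectors (g11, g12, g21, g22)
element_shape_inverse <- function(canvas, nodes = canvas$nodes) {
  el <- canvas$elements
  p1 <- nodes[el[, 1], , drop = FALSE]
  p2 <- nodes[el[, 2], , drop = FALSE]
  p3 <- nodes[el[, 3], , drop = FALSE]
  s11 <- p1[, 1] - p3[, 1]; s12 <- p2[, 1] - p3[, 1]
  s21 <- p1[, 2] - p3[, 2]; s22 <- p2[, 2] - p3[, 2]
  det <- s11 * s22 - s12 * s21
  list(g11 = s22 / det, g12 = -s12 / det,
       g21 = -s21 / det, g22 = s11 / det, det = det)
}

#' Specified growth per element
#'
#' Container for per-element specified growth: rates parallel and
#' perpendicular to the local polarity axis, and the polarity angle.
#'
#' @param k_par,k_per nonnegative rates (per hour), length 1 or one per
#'   element
#' @param angle polarity angle per element (radians, direction of the
#'   parallel axis)
#' @param n_elem number of elements (for recycling scalars)
#' @return list of class \code{"specified_growth"}
#' @export
specified_growth_field <- function(k_par, k_per, angle, n_elem) {
  if (any(k_par < -1e-12) || any(k_per < -1e-12))
    stop("specified growth rates must be nonnegative")
  structure(list(k_par = rep_len(k_par, n_elem),
                 k_per = rep_len(k_per, n_elem),
                 angle = rep_len(angle, n_elem)),
            class = "specified_growth")
}

#' Advance the canvas by one growth step
#'
#' Applies per-element target stretches (1 + k_par dt) along the polarity
#' axis and (1 + k_per dt) perpendicular to it, and relaxes the node
#' positions to the least-squares-compatible configuration (see package
#' vignette).  Exact for spatially uniform specified growth.
#'
#' @param canvas a \code{leaf_canvas}
#' @param spec a \code{\link{specified_growth_field}}
#' @param dt time step (h), > 0
#' @return the deformed \code{leaf_canvas}
#' @export
step_growth <- function(canvas, spec, dt) {
  stopifnot(dt > 0)
  m <- nrow(canvas$elements)
  stopifnot(length(spec$k_par) == m)
  ar <- element_areas(canvas)
  G <- element_shape_inverse(canvas)

  # target deformation gradients
  ca <- cos(spec$angle); sa <- sin(spec$angle)
  l1 <- 1 + spec$k_par * dt; l2 <- 1 + spec$k_per * dt
  f11 <- l1 * ca * ca + l2 * sa * sa
  f22 <- l1 * sa * sa + l2 * ca * ca
  f12 <- (l1 - l2) * ca * sa
  f21 <- f12

  el <- canvas$elements
  # linear-functional coefficients per element for F columns j = 1, 2:
  # c_j = (G[1,j], G[2,j], -G[1,j]-G[2,j]) over nodes (v1, v2, v3)
  c1 <- cbind(G$g11, G$g21, -G$g11 - G$g21)  # column 1 of F
  c2 <- cbind(G$g12, G$g22, -G$g12 - G$g22)  # column 2 of F
  w <- ar

  # normal matrix N = sum_e A_e (c1 c1' + c2 c2') scattered to nodes
  ii <- jj <- vv <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- el[, a]; jj[[k]] <- el[, b]
    vv[[k]] <- w * (c1[, a] * c1[, b] + c2[, a] * c2[, b])
  }
  n <- nrow(canvas$nodes)
  N <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(n, n))
  # right-hand sides: rows of F_t
  bx <- by <- numeric(n)
  for (a in 1:3) {
    contrib_x <- w * (c1[, a] * f11 + c2[, a] * f12)
    contrib_y <- w * (c1[, a] * f21 + c2[, a] * f22)
    bx <- bx + unname(tapply_add(contrib_x, el[, a], n))
    by <- by + unname(tapply_add(contrib_y, el[, a], n))
  }

  # pin the base-midline node (translation nullspace)
  pin <- canvas$midline_nodes[1L]
  keep <- setdiff(seq_len(n), pin)
  p_pin <- canvas$nodes[pin, ]
  Nr <- N[keep, keep, drop = FALSE]
  bxr <- bx[keep] - N[keep, pin] * p_pin[1]
  byr <- by[keep] - N[keep, pin] * p_pin[2]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Nr), LDL = FALSE)
  xy <- cbind(as.numeric(Matrix::solve(ch, bxr)),
              as.numeric(Matrix::solve(ch, byr)))
  new_nodes <- canvas$nodes
  new_nodes[keep, ] <- xy
  new_nodes[pin, ] <- p_pin

  if (any(element_areas(canvas, new_nodes) <= 0))
    stop("element inversion during growth relaxation; reduce dt")
  canvas$nodes <- new_nodes
  canvas
}

# sum `x` into bins `idx` over 1..n (sparse accumulation)
tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  acc <- rowsum(x, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Resultant growth rates between two canvas states
#'
#' Computes the per-element deformation gradient between two
#' topology-sharing canvas configurations and returns areal and
#' directional (midline-parallel / midline-perpendicular) relative
#' elemental growth rates.
#'
#' The midline axis is material: the instantaneous image of the initial
#' proximodistal symmetry axis in each element (not a fixed laboratory
#' axis).
#'
#' @param canvas_t1,canvas_t2 canvases sharing mesh topology
#' @param dt elapsed time (h), > 0
#' @return data.frame with columns \code{areal}, \code{parallel},
#'   \code{perpendicular} (per hour, one row per element)
#' @export
resultant_growth <- function(canvas_t1, canvas_t2, dt) {
  stopifnot(dt > 0)
  if (!identical(dim(canvas_t1$elements), dim(canvas_t2$elements)))
    stop("canvases do not share mesh topology")
  Fel <- deformation_gradients(canvas_t1$nodes, canvas_t2$nodes, canvas_t1)
  axis <- midline_axis_elements(canvas_t1)
  rates <- tensor_growth_rates(Fel, axis, dt)
  as.data.frame(rates)
}

# per-element deformation gradients F between two node configurations
deformation_gradients <- function(nodes_old, nodes_new, canvas) {
  G <- element_shape_inverse(canvas, nodes_old)
  el <- canvas$elements
  q1 <- nodes_new[el[, 1], , drop = FALSE]
  q2 <- nodes_new[el[, 2], , drop = FALSE]
  q3 <- nodes_new[el[, 3], , drop = FALSE]
  d11 <- q1[, 1] - q3[, 1]; d12 <- q2[, 1] - q3[, 1]
  d21 <- q1[, 2] - q3[, 2]; d22 <- q2[, 2] - q3[, 2]
  list(f11 = d11 * G$g11 + d12 * G$g21,
       f12 = d11 * G$g12 + d12 * G$g22,
       f21 = d21 * G$g11 + d22 * G$g21,
       f22 = d21 * G$g12 + d22 * G$g22)
}

# unit midline (proximodistal) axis per element: image of the initial
# +v direction under the deformation from the initial configuration
midline_axis_elements <- function(canvas) {
  Ftot <- deformation_gradients(canvas$nodes0, canvas$nodes, canvas)
  ax <- cbind(Ftot$f12, Ftot$f22)  # F %*% (0, 1)
  ax / sqrt(rowSums(ax^2))
}

# areal and directional log rates from per-element F and a unit axis.
# Directional rates are projections of the log right-stretch tensor,
# rate_a = a' ln(U) a / dt with U = sqrt(F'F), so that
# parallel + perpendicular = areal holds exactly (trace identity), and
# rigid rotations give zero.
tensor_growth_rates <- function(Fel, axis, dt) {
  detF <- Fel$f11 * Fel$f22 - Fel$f12 * Fel$f21
  # right Cauchy-Green C = F'F;  ln U = ln(C) / 2
  c11 <- Fel$f11^2 + Fel$f21^2
  c12 <- Fel$f11 * Fel$f12 + Fel$f21 * Fel$f22
  c22 <- Fel$f12^2 + Fel$f22^2
  half_tr <- (c11 + c22) / 2
  disc <- sqrt(pmax(0, (c11 - c22)^2 / 4 + c12^2))
  lam1 <- half_tr + disc
  lam2 <- pmax(half_tr - disc, .Machine$double.xmin)
  # unit eigenvector of lam1: (c12, lam1 - c11); degenerate only when C
  # is (numerically) isotropic, where any axis serves
  v1x <- c12
  v1y <- lam1 - c11
  nv <- sqrt(v1x^2 + v1y^2)
  iso <- nv <= 1e-14 * pmax(lam1, 1)
  v1x <- ifelse(iso, 1, v1x / ifelse(nv == 0, 1, nv))
  v1y <- ifelse(iso, 0, v1y / ifelse(nv == 0, 1, nv))
  a1 <- axis[, 1]; a2 <- axis[, 2]
  pa <- (a1 * v1x + a2 * v1y)^2        # |<a, v1>|^2
  pb <- (a2 * v1x - a1 * v1y)^2        # perpendicular axis projection
  l1 <- log(lam1) / 2; l2 <- log(lam2) / 2
  list(areal = log(detF) / dt,
       parallel = (pa * l1 + (1 - pa) * l2) / dt,
       perpendicular = (pb * l1 + (1 - pb) * l2) / dt)
}
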
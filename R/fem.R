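# Linear (P1) finite-element operators on the triangulated canvas, used
# for diffusion-decay of the mobile factors (POL during setup, PMF during
# growth).  Mass is lumped; time stepping is implicit Euler, which is
# unconditionally stable so no internal sub-stepping is needed.

# lumped mass vector (um^2) and stiffness matrix (dimensionless * area)
fem_operators <- function(canvas, nodes = canvas$nodes) {
  el <- canvas$elements
  ar <- element_areas(canvas, nodes)
  n <- nrow(nodes)
  mass <- tapply_add(rep(ar / 3, 3L), as.integer(el), n)
  p1 <- nodes[el[, 1], , drop = FALSE]
  p2 <- nodes[el[, 2], , drop = FALSE]
  p3 <- nodes[el[, 3], , drop = FALSE]
  # gradients of the barycentric basis functions
  b1 <- cbind(p2[, 2] - p3[, 2], p3[, 1] - p2[, 1]) / (2 * ar)
  b2 <- cbind(p3[, 2] - p1[, 2], p1[, 1] - p3[, 1]) / (2 * ar)
  b3 <- cbind(p1[, 2] - p2[, 2], p2[, 1] - p1[, 1]) / (2 * ar)
  grads <- list(b1, b2, b3)
  ii <- jj <- vv <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- el[, a]; jj[[k]] <- el[, b]
    vv[[k]] <- ar * rowSums(grads[[a]] * grads[[b]])
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(n, n))
  list(mass = mass, K = K)
}

# one implicit diffusion-decay step:
#   (M (1/dt + mu) + D K) c_new = M c_old / dt, with Dirichlet nodes held
# at fixed values.  D in um^2/h, mu in 1/h.
diffusion_step <- function(canvas, conc, D, mu, dt, dirichlet_idx,
                           dirichlet_val, ops = NULL) {
  if (is.null(ops)) ops <- fem_operators(canvas)
  n <- length(conc)
  A <- Matrix::Diagonal(n, ops$mass * (1 / dt + mu)) + D * ops$K
  b <- ops$mass * conc / dt
  free <- setdiff(seq_len(n), dirichlet_idx)
  b_free <- b[free] - as.numeric(A[free, dirichlet_idx, drop = FALSE] %*%
                                   rep_len(dirichlet_val, length(dirichlet_idx)))
  out <- conc
  out[dirichlet_idx] <- dirichlet_val
  out[free] <- as.numeric(Matrix::solve(A[free, free, drop = FALSE], b_free))
  out
}

# steady state of diffusion-decay with Dirichlet source:
#   (mu M + D K) c = 0 on free nodes
diffusion_steady <- function(canvas, D, mu, dirichlet_idx, dirichlet_val,
                             ops = NULL) {
  if (is.null(ops)) ops <- fem_operators(canvas)
  n <- nrow(canvas$nodes)
  A <- Matrix::Diagonal(n, ops$mass * mu) + D * ops$K
  free <- setdiff(seq_len(n), dirichlet_idx)
  b_free <- -as.numeric(A[free, dirichlet_idx, drop = FALSE] %*%
                          rep_len(dirichlet_val, length(dirichlet_idx)))
  out <- numeric(n)
  out[dirichlet_idx] <- dirichlet_val
  out[free] <- as.numeric(Matrix::solve(A[free, free, drop = FALSE], b_free))
  out
}
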
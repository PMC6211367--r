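# Synthetic tracking data with known ground truth: exported from a
# simulation trajectory, or generated by a simulator-free parametric
# process (prescribed growth field + threshold-area division on an
# irregular polygon packing).

#' Export a simulation trajectory as a tracking dataset
#'
#' Samples the trajectory's snapshots at a fixed interval, exports the
#' v-cell vertices as tracked points (optionally with isotropic Gaussian
#' click noise), carries lineage links and region labels through, and
#' can remove a contiguous patch of cells (occlusion-style dropout).
#' The simulation's own division-event table is attached as ground
#' truth.
#'
#' @param sim a \code{leaf_sim}
#' @param sampling_interval h between exported timepoints (must be a
#'   multiple of the snapshot spacing present in the trajectory)
#' @param noise_sd isotropic Gaussian vertex noise (um)
#' @param dropout approximate fraction of first-timepoint cells removed
#'   as one connected patch (with all their descendants)
#' @param seed RNG seed for noise/dropout
#' @return a \code{\link{tracking_dataset}} with a \code{ground_truth}
#'   attribute (the simulation event table)
#' @export
from_trajectory <- function(sim, sampling_interval = 12, noise_sd = 0,
                            dropout = 0, seed = 1) {
  stopifnot(inherits(sim, "leaf_sim"))
  set.seed(seed)
  times <- vapply(sim$snapshots, `[[`, numeric(1), "t")
  keep_t <- times[1] + sampling_interval *
    (0:floor((max(times) - times[1]) / sampling_interval))
  sel <- vapply(keep_t, function(t) which.min(abs(times - t)), integer(1))
  sel <- unique(sel[abs(times[sel] - keep_t) < 1e-6])
  if (length(sel) < 2) stop("sampling grid not covered by trajectory snapshots")

  drop_lineages <- integer(0)
  if (dropout > 0) {
    s1 <- sim$snapshots[[sel[1]]]
    nb <- neighbour_list(s1$cells)
    n_drop <- max(1L, round(dropout * length(s1$cells)))
    seed_cell <- sample.int(length(s1$cells), 1)
    patch <- seed_cell
    frontier <- seed_cell
    while (length(patch) < n_drop && length(frontier)) {
      frontier <- setdiff(unique(unlist(nb[frontier])), patch)
      patch <- c(patch, frontier)
    }
    patch <- patch[seq_len(min(n_drop, length(patch)))]
    drop_lineages <- descendants_of(sim$events, s1$lineage[patch])
  }

  verts <- list(); cells <- list()
  for (i in sel) {
    s <- sim$snapshots[[i]]
    keep <- !(s$lineage %in% drop_lineages)
    used <- sort(unique(unlist(s$cells[keep])))
    pos <- s$vt_pos[used, , drop = FALSE]
    if (noise_sd > 0)
      pos <- pos + matrix(stats::rnorm(length(pos), 0, noise_sd), ncol = 2)
    verts[[length(verts) + 1L]] <-
      data.frame(vertex_id = used, x = pos[, 1], y = pos[, 2])
    cells[[length(cells) + 1L]] <- data.frame(
      cell_id = s$lineage[keep], lineage_id = s$lineage[keep],
      region = s$region[keep], layer = s$layer[keep],
      vertices = vapply(s$cells[keep], paste, character(1), collapse = " "))
  }
  ev <- sim$events
  ev <- ev[!(ev$mother_lineage %in% drop_lineages), , drop = FALSE]
  plb <- vapply(sel, function(i) plb_y_position(sim, i), numeric(1))
  ds <- tracking_dataset(
    timepoints = times[sel], vertices = verts, cells = cells,
    lineage = if (nrow(ev)) data.frame(parent = ev$mother_lineage,
                                       daughter1 = ev$daughter1,
                                       daughter2 = ev$daughter2,
                                       time = ev$time)
              else data.frame(parent = integer(0), daughter1 = integer(0),
                              daughter2 = integer(0), time = numeric(0)),
    plb_position = plb, midline_axis = c(0, 1),
    metadata = list(source = "trajectory", noise_sd = noise_sd,
                    dropout = dropout, seed = seed,
                    sampling_interval = sampling_interval))
  attr(ds, "ground_truth") <- sim$events
  ds
}

# y-position of the anchored petiole-lamina boundary at snapshot i
plb_y_position <- function(sim, i) {
  s <- sim$snapshots[[i]]
  mean(s$nodes[sim$tissue$cv$plb_nodes, 2])
}

# adjacency (by shared edge) among a list of vertex cycles
neighbour_list <- function(cycles) {
  edge_owner <- new.env(parent = emptyenv())
  for (i in seq_along(cycles)) {
    cyc <- cycles[[i]]; n <- length(cyc)
    for (k in seq_len(n)) {
      a <- cyc[k]; b <- cyc[k %% n + 1]
      ky <- paste0(min(a, b), "_", max(a, b))
      edge_owner[[ky]] <- c(edge_owner[[ky]], i)
    }
  }
  nb <- vector("list", length(cycles))
  for (ky in ls(edge_owner)) {
    ow <- edge_owner[[ky]]
    if (length(ow) == 2) {
      nb[[ow[1]]] <- c(nb[[ow[1]]], ow[2])
      nb[[ow[2]]] <- c(nb[[ow[2]]], ow[1])
    }
  }
  nb
}

# all descendants (inclusive) of a set of lineage ids given an event table
descendants_of <- function(events, ids) {
  out <- ids
  repeat {
    more <- events[events$mother_lineage %in% out, c("daughter1", "daughter2")]
    new <- setdiff(unlist(more), out)
    if (!length(new)) break
    out <- c(out, new)
  }
  out
}

# ---- parametric generator ---------------------------------------------

# flat (anchor-free) tissue: brick packing of a rectangle [0,W] x [0,H]
flat_brick_tissue <- function(width, height, n_cu, n_cv, jitter = 0.2) {
  tis <- new.env(parent = emptyenv())
  tis$cv <- NULL
  tis$n_vert <- 0L
  tis$vt_elem <- integer(0)
  tis$vt_b <- matrix(0, 0, 3)
  tis$vt_boundary <- logical(0)
  tis$vert_inc <- list()
  tis$cells <- list(); tis$alive <- logical(0)
  tis$region <- character(0); tis$layer <- character(0)
  tis$lineage <- integer(0); tis$parent <- integer(0)
  tis$birth <- numeric(0); tis$target <- numeric(0)
  tis$competent <- logical(0)
  tis$next_lineage <- 1L
  tis$spaces <- list(); tis$space_birth <- numeric(0); tis$space_r <- numeric(0)
  tis$events <- list()
  tis$elem_cell <- integer(0)

  du <- width / n_cu; dv <- height / n_cv
  cuts <- lapply(seq_len(n_cv) - 1L, function(j) {
    if (j %% 2 == 0) seq(0, width, by = du)
    else c(0, seq(du / 2, width - du / 2, by = du), width)
  })
  key_env <- new.env(parent = emptyenv())
  px <- py <- numeric(0); bnd <- logical(0)
  register <- function(j, u) {
    ky <- sprintf("%d|%.8f", j, u)
    if (!is.null(key_env[[ky]])) return(key_env[[ky]])
    id <- length(px) + 1L
    on_side <- u < 1e-9 || u > width - 1e-9
    on_cap <- j == 0L || j == n_cv
    uu <- u; vv <- j * dv
    if (!on_side && !on_cap) {
      uu <- u + stats::runif(1, -jitter, jitter) * du
      vv <- vv + stats::runif(1, -jitter, jitter) * dv
    }
    px[id] <<- uu; py[id] <<- vv; bnd[id] <<- on_side || on_cap
    key_env[[ky]] <- id
    id
  }
  for (j in 0:n_cv) {
    below <- if (j > 0) cuts[[j]] else numeric(0)
    above <- if (j < n_cv) cuts[[j + 1L]] else numeric(0)
    for (u in sort(unique(c(below, above)))) register(j, u)
  }
  get_id <- function(j, u) key_env[[sprintf("%d|%.8f", j, u)]]
  span <- function(j, ua, ub) {
    us <- sort(unique(c(if (j > 0) cuts[[j]] else numeric(0),
                        if (j < n_cv) cuts[[j + 1L]] else numeric(0))))
    us <- us[us >= ua - 1e-9 & us <= ub + 1e-9]
    vapply(us, function(u) get_id(j, u), integer(1))
  }
  tis$vt_pos <- NULL
  for (j0 in seq_len(n_cv)) {
    cu <- cuts[[j0]]
    for (k in seq_len(length(cu) - 1L)) {
      bot <- span(j0 - 1L, cu[k], cu[k + 1L])
      top <- span(j0, cu[k], cu[k + 1L])
      cyc <- c(bot, rev(top))
      cyc <- cyc[!duplicated(cyc)]
      cid <- length(tis$cells) + 1L
      tis$cells[[cid]] <- cyc
      tis$alive[cid] <- TRUE
      tis$region[cid] <- "lamina"; tis$layer[cid] <- "epidermis"
      tis$lineage[cid] <- tis$next_lineage
      tis$next_lineage <- tis$next_lineage + 1L
      tis$parent[cid] <- NA_integer_; tis$birth[cid] <- 0
      tis$target[cid] <- NA_real_; tis$competent[cid] <- TRUE
    }
  }
  n <- length(px)
  tis$n_vert <- n
  tis$vt_elem <- rep(NA_integer_, n)
  tis$vt_b <- matrix(NA_real_, n, 3)
  tis$vt_boundary <- bnd
  tis$vt_pos <- cbind(px, py)
  tis$vert_inc <- rep(list(integer(0)), n)
  for (cid in seq_along(tis$cells)) add_incidence(tis, tis$cells[[cid]], cid)
  tis
}

#' Generate a parametric synthetic tracking dataset
#'
#' Simulator-free ground-truth process: an irregular polygon packing on
#' a rectangle grows under a prescribed growth-rate field (positions
#' advect as \code{dp/dt = diag(kx, ky) (p - origin)}; with uniform
#' rates the areal growth rate of every cell is exactly kx + ky), while
#' cells divide by the noisy shortest-wall rule once their area exceeds
#' a normal threshold with mean \code{abar_fun(x, y)} and relative sd
#' \code{sigma_frac}.  Vertex noise is added at export.
#'
#' @param width,height rectangle size (um)
#' @param n_cu,n_cv initial packing
#' @param k_x,k_y growth rates (1/h), scalars
#' @param abar_fun function(x, y) -> mean division threshold (um^2), or
#'   NULL to disable division
#' @param sigma_frac relative threshold sd
#' @param t_end duration (h); \code{dt} internal step
#' @param sampling_interval export interval (h)
#' @param noise_sd vertex click noise (um)
#' @param seed RNG seed
#' @param dt internal step (h)
#' @return a \code{\link{tracking_dataset}} with a \code{ground_truth}
#'   attribute: list(k_x, k_y, abar_fun, events)
#' @export
parametric_generate <- function(width = 300, height = 300, n_cu = 8,
                                n_cv = 8, k_x = 0.02, k_y = 0.02,
                                abar_fun = NULL, sigma_frac = 0.2,
                                t_end = 24, sampling_interval = 6,
                                noise_sd = 0, seed = 1, dt = 1) {
  set.seed(seed)
  tis <- flat_brick_tissue(width, height, n_cu, n_cv)
  dp <- division_params("epidermis", sigma_frac = sigma_frac)
  gf <- function(cen, region) abar_fun(cen[1], cen[2])
  if (!is.null(abar_fun)) {
    cens <- cell_centroids(tis)
    for (i in seq_along(tis$cells)) {
      eps <- if (sigma_frac > 0) max(stats::rnorm(1, 1, sigma_frac), 0.3) else 1
      tis$target[i] <- eps * abar_fun(cens[i, 1], cens[i, 2])
    }
  }
  record <- list(); rec_t <- numeric(0)
  take <- function(t) {
    alive <- which(tis$alive)
    used <- sort(unique(unlist(tis$cells[alive])))
    pos <- tis$vt_pos[used, , drop = FALSE]
    if (noise_sd > 0)
      pos <- pos + matrix(stats::rnorm(length(pos), 0, noise_sd), ncol = 2)
    list(vertices = data.frame(vertex_id = used, x = pos[, 1], y = pos[, 2]),
         cells = data.frame(cell_id = tis$lineage[alive],
                            lineage_id = tis$lineage[alive],
                            region = tis$region[alive],
                            layer = tis$layer[alive],
                            vertices = vapply(tis$cells[alive], paste,
                                              character(1), collapse = " ")))
  }
  record[[1]] <- take(0); rec_t[1] <- 0
  t <- 0
  next_out <- sampling_interval
  while (t < t_end - 1e-9) {
    step <- min(dt, t_end - t)
    grow <- cbind(exp(k_x * step), exp(k_y * step))
    if (min(grow) <= 0) stop("growth field folds the domain")
    tis$vt_pos <- cbind(tis$vt_pos[, 1] * grow[1], tis$vt_pos[, 2] * grow[2])
    t <- t + step
    if (!is.null(abar_fun)) attempt_divisions(tis, t, gf, dp)
    if (t >= next_out - 1e-9) {
      record[[length(record) + 1L]] <- take(t)
      rec_t[length(rec_t) + 1L] <- t
      next_out <- next_out + sampling_interval
    }
  }
  ev <- if (length(tis$events)) do.call(rbind, tis$events) else
    data.frame(mother_lineage = integer(0), daughter1 = integer(0),
               daughter2 = integer(0), time = numeric(0),
               mother_area = numeric(0))
  ds <- tracking_dataset(
    timepoints = rec_t,
    vertices = lapply(record, `[[`, "vertices"),
    cells = lapply(record, `[[`, "cells"),
    lineage = if (nrow(ev)) data.frame(parent = ev$mother_lineage,
                                       daughter1 = ev$daughter1,
                                       daughter2 = ev$daughter2,
                                       time = ev$time)
              else data.frame(parent = integer(0), daughter1 = integer(0),
                              daughter2 = integer(0), time = numeric(0)),
    plb_position = rep(0, length(rec_t)), midline_axis = c(0, 1),
    metadata = list(source = "parametric", seed = seed,
                    noise_sd = noise_sd,
                    sampling_interval = sampling_interval))
  attr(ds, "ground_truth") <- list(k_x = k_x, k_y = k_y,
                                   abar_fun = abar_fun, events = ev)
  ds
}
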
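# Intercellular spaces (subepidermal models): small empty triangles that
# replace three-way wall junctions and then expand autonomously.  Thirty
# spaces are introduced at 120 h and further junctions are replaced at
# 11 per hour.  Each space's vertices move away from its centre at 1.25%
# of its size per hour (areal growth 2.5% per hour); its centre is
# carried along with the tissue.

# vertices eligible for replacement: interior three-way junctions of
# living cells, not already adjacent to a space
eligible_space_vertices <- function(tis) {
  ok <- logical(tis$n_vert)
  for (v in seq_len(tis$n_vert)) {
    inc <- tis$vert_inc[[v]]
    ok[v] <- length(inc) == 3 && all(inc > 0) && !tis$vt_boundary[v] &&
      all(tis$alive[inc])
  }
  which(ok)
}

# replace junction vertex `vid` by an (approximately equilateral)
# triangle of area `area0`, vertices placed along the three incident
# walls; returns TRUE on success
replace_vertex_with_space <- function(tis, vid, t, area0 = 2) {
  inc <- tis$vert_inc[[vid]]
  if (length(inc) != 3 || any(inc <= 0)) return(FALSE)
  p0 <- tis$vt_pos[vid, ]
  # incident wall directions: within each cell, vid's two cycle
  # neighbours; union over the three cells = three wall partners
  partners <- integer(0)
  for (cid in inc) {
    cyc <- tis$cells[[cid]]
    i <- match(vid, cyc); n <- length(cyc)
    partners <- c(partners, cyc[if (i == 1) n else i - 1], cyc[i %% n + 1])
  }
  partners <- unique(partners)
  if (length(partners) != 3) return(FALSE)
  dirs <- tis$vt_pos[partners, , drop = FALSE] -
    matrix(p0, 3, 2, byrow = TRUE)
  dlen <- sqrt(rowSums(dirs^2))
  if (any(dlen < 1e-9)) return(FALSE)
  dirs <- dirs / dlen
  # triangle with vertices at p0 + rho * d_i, area = rho^2/2 * |sum of
  # pairwise crosses| (vertices ordered by angle)
  ang <- atan2(dirs[, 2], dirs[, 1])
  ord <- order(ang)
  dirs <- dirs[ord, , drop = FALSE]; partners <- partners[ord]
  dlen <- dlen[ord]
  cr <- function(a, b) a[1] * b[2] - a[2] * b[1]
  s2 <- cr(dirs[1, ], dirs[2, ]) + cr(dirs[2, ], dirs[3, ]) +
    cr(dirs[3, ], dirs[1, ])
  if (s2 <= 1e-6) return(FALSE)
  rho <- sqrt(2 * area0 / s2)
  if (rho > 0.4 * min(dlen)) return(FALSE)  # would squash a tiny cell
  newp <- matrix(p0, 3, 2, byrow = TRUE) + rho * dirs
  anch <- locate_points(tis$cv, newp)
  w <- add_vertices(tis, anch)
  tis$vt_pos <- rbind(tis$vt_pos, newp)
  sid <- length(tis$spaces) + 1L
  # each cell between walls i and i+1 replaces vid by (w_{i+1}, w_i)
  # seen in its own orientation; find per cell by matching its two
  # partner walls
  for (cid in inc) {
    cyc <- tis$cells[[cid]]
    i <- match(vid, cyc); n <- length(cyc)
    prev <- cyc[if (i == 1) n else i - 1]
    nxt <- cyc[i %% n + 1]
    wp <- w[match(prev, partners)]
    wn <- w[match(nxt, partners)]
    cyc <- append(cyc[-i], c(wp, wn), after = if (i == 1) n - 1 else i - 1)
    tis$cells[[cid]] <- cyc
    add_incidence(tis, c(wp, wn), cid)
  }
  drop_incidence(tis, vid, inc[1]); drop_incidence(tis, vid, inc[2])
  drop_incidence(tis, vid, inc[3])
  # space cycle: counterclockwise by construction (angle order)
  tis$spaces[[sid]] <- w
  tis$space_birth[sid] <- t
  tis$space_r[sid] <- rho
  add_incidence(tis, w, -sid)
  TRUE
}

# introduce spaces per schedule: 30 at the initiation time, then at
# `rate` per hour, at uniformly chosen eligible junctions
manage_spaces <- function(tis, t, dt, init_t = 120, init_n = 30, rate = 11) {
  n_new <- 0L
  if (is.null(tis$space_init_done)) tis$space_init_done <- FALSE
  if (is.null(tis$space_carry)) tis$space_carry <- 0
  if (!tis$space_init_done && t >= init_t) {
    n_new <- init_n
    tis$space_init_done <- TRUE
  } else if (tis$space_init_done) {
    tis$space_carry <- tis$space_carry + rate * dt
    n_new <- floor(tis$space_carry)
    tis$space_carry <- tis$space_carry - n_new
  }
  if (n_new == 0) return(invisible(tis))
  elig <- eligible_space_vertices(tis)
  made <- 0L
  while (made < n_new && length(elig)) {
    pick <- elig[sample.int(length(elig), 1)]
    if (replace_vertex_with_space(tis, pick, t)) made <- made + 1L
    elig <- setdiff(elig, pick)
  }
  invisible(tis)
}

# enforce autonomous space expansion after tissue advection: rescale the
# vertex offsets about the advected centre so the space's size grows by
# (1 + 0.0125 dt) per step, then re-anchor the vertices
advance_spaces <- function(tis, dt, lin_rate = 0.0125) {
  if (!length(tis$spaces)) return(invisible(tis))
  for (s in seq_along(tis$spaces)) {
    w <- tis$spaces[[s]]
    P <- tis$vt_pos[w, , drop = FALSE]
    cen <- colMeans(P)
    off <- P - matrix(cen, nrow(P), 2, byrow = TRUE)
    r_adv <- mean(sqrt(rowSums(off^2)))
    r_new <- tis$space_r[s] * (1 + lin_rate * dt)
    newp <- matrix(cen, nrow(P), 2, byrow = TRUE) + off * (r_new / r_adv)
    anch <- locate_points(tis$cv, newp)
    tis$vt_elem[w] <- anch$elem
    tis$vt_b[w, ] <- anch$b
    tis$vt_pos[w, ] <- newp
    tis$space_r[s] <- r_new
  }
  invisible(tis)
}

# total space area (um^2)
space_areas <- function(tis) {
  vapply(tis$spaces, function(w)
    polygon_area(tis$vt_pos[w, , drop = FALSE]), numeric(1))
}
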
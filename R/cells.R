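# Virtual cells (v-cells) anchored to the canvas.
#
# The tissue state is an environment holding a shared vertex store
# (anchor = element index + barycentric weights; positions are always
# derived from the current canvas nodes), polygonal cells referencing
# vertex ids counterclockwise, per-cell metadata, intercellular spaces
# (growing triangles sharing vertices with their flanking cells), and a
# vertex -> polygon incidence index.  Cells plus spaces tile the canvas
# exactly: every wall vertex is shared by all polygons meeting there, and
# subdivision points are inserted into every incident cycle.

# map parameter coordinates (u in [-1,1], v in [0,1]) to mesh anchors
param_to_anchor <- function(canvas, u, v) {
  n_u <- canvas$n_u; n_v <- canvas$n_v
  su_g <- (u + 1) / 2 * n_u
  sv_g <- v * n_v
  i <- pmin(pmax(floor(su_g - 1e-12), 0), n_u - 1)
  j <- pmin(pmax(floor(sv_g - 1e-12), 0), n_v - 1)
  su <- su_g - i; sv <- sv_g - j
  left <- i < n_u / 2
  first <- ifelse(left, su >= sv, su + sv <= 1)
  elem <- 2L * (j * n_u + i) + ifelse(first, 1L, 2L)
  b <- matrix(0, length(u), 3)
  # left quads: (a,b,c) / (a,c,d); right quads: (a,b,d) / (b,c,d)
  lf <- left & first;   b[lf, ] <- cbind(1 - su, su - sv, sv)[lf, , drop = FALSE]
  ls <- left & !first;  b[ls, ] <- cbind(1 - sv, su, sv - su)[ls, , drop = FALSE]
  rf <- !left & first;  b[rf, ] <- cbind(1 - su - sv, su, sv)[rf, , drop = FALSE]
  rs <- !left & !first; b[rs, ] <- cbind(1 - sv, su + sv - 1, 1 - su)[rs, , drop = FALSE]
  b <- pmax(b, 0)
  b <- b / rowSums(b)
  list(elem = as.integer(elem), b = b)
}

# locate physical points in the current mesh (brute force over elements,
# vectorized per point); returns anchors
locate_points <- function(canvas, pts) {
  el <- canvas$elements
  nodes <- canvas$nodes
  p1 <- nodes[el[, 1], , drop = FALSE]
  p2 <- nodes[el[, 2], , drop = FALSE]
  p3 <- nodes[el[, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  n <- nrow(pts)
  elem <- integer(n); b <- matrix(0, n, 3)
  for (q in seq_len(n)) {
    dx <- pts[q, 1]; dy <- pts[q, 2]
    b2 <- ((dx - p1[, 1]) * (p3[, 2] - p1[, 2]) -
             (p3[, 1] - p1[, 1]) * (dy - p1[, 2])) / det
    b3 <- ((p2[, 1] - p1[, 1]) * (dy - p1[, 2]) -
             (dx - p1[, 1]) * (p2[, 2] - p1[, 2])) / det
    b1 <- 1 - b2 - b3
    score <- pmin(b1, b2, b3)
    e <- which.max(score)
    bb <- pmax(c(b1[e], b2[e], b3[e]), 0)
    elem[q] <- e
    b[q, ] <- bb / sum(bb)
  }
  list(elem = elem, b = b)
}

# ---- tissue state ------------------------------------------------------

add_vertices <- function(tis, anchors, boundary = FALSE) {
  k <- length(anchors$elem)
  ids <- tis$n_vert + seq_len(k)
  tis$vt_elem <- c(tis$vt_elem, anchors$elem)
  tis$vt_b <- rbind(tis$vt_b, anchors$b)
  tis$vt_boundary <- c(tis$vt_boundary, rep_len(boundary, k))
  tis$n_vert <- tis$n_vert + k
  for (id in ids) tis$vert_inc[[id]] <- integer(0)
  ids
}

# recompute all vertex positions from anchors and current canvas nodes
refresh_positions <- function(tis) {
  el <- tis$cv$elements[tis$vt_elem, , drop = FALSE]
  nd <- tis$cv$nodes
  b <- tis$vt_b
  tis$vt_pos <- cbind(
    b[, 1] * nd[el[, 1], 1] + b[, 2] * nd[el[, 2], 1] + b[, 3] * nd[el[, 3], 1],
    b[, 1] * nd[el[, 1], 2] + b[, 2] * nd[el[, 2], 2] + b[, 3] * nd[el[, 3], 2])
  invisible(tis)
}

# material proximodistal parameter of vertices (barycentric mean of the
# element nodes' v coordinates)
vertex_v_param <- function(tis, ids = seq_len(tis$n_vert)) {
  el <- tis$cv$elements[tis$vt_elem[ids], , drop = FALSE]
  vv <- tis$cv$param[, "v"]
  b <- tis$vt_b[ids, , drop = FALSE]
  b[, 1] * vv[el[, 1]] + b[, 2] * vv[el[, 2]] + b[, 3] * vv[el[, 3]]
}

polygon_area <- function(P) {
  n <- nrow(P)
  i2 <- c(2:n, 1)
  0.5 * sum(P[, 1] * P[i2, 2] - P[i2, 1] * P[, 2])
}

polygon_centroid <- function(P) {
  n <- nrow(P)
  i2 <- c(2:n, 1)
  cr <- P[, 1] * P[i2, 2] - P[i2, 1] * P[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(P))
  c(sum((P[, 1] + P[i2, 1]) * cr), sum((P[, 2] + P[i2, 2]) * cr)) / (6 * a)
}

# areas of all alive cells (um^2)
cell_areas <- function(tis) {
  pos <- tis$vt_pos
  vapply(seq_along(tis$cells), function(i) {
    if (!tis$alive[i]) return(NA_real_)
    polygon_area(pos[tis$cells[[i]], , drop = FALSE])
  }, numeric(1))
}

cell_centroids <- function(tis) {
  pos <- tis$vt_pos
  out <- matrix(NA_real_, length(tis$cells), 2)
  for (i in seq_along(tis$cells)) {
    if (tis$alive[i])
      out[i, ] <- polygon_centroid(pos[tis$cells[[i]], , drop = FALSE])
  }
  out
}

# mean material v parameter per cell (for proximodistal distances)
cell_v_param <- function(tis) {
  vv <- vertex_v_param(tis)
  vapply(seq_along(tis$cells), function(i) {
    if (!tis$alive[i]) return(NA_real_)
    mean(vv[tis$cells[[i]]])
  }, numeric(1))
}

add_incidence <- function(tis, ids, owner) {
  for (id in ids) tis$vert_inc[[id]] <- c(tis$vert_inc[[id]], owner)
}

drop_incidence <- function(tis, ids, owner) {
  for (id in ids) {
    inc <- tis$vert_inc[[id]]
    tis$vert_inc[[id]] <- inc[inc != owner]
  }
}

# ---- initial packing ---------------------------------------------------

#' Initialize the v-cell tissue on a canvas
#'
#' Superimposes an irregular "brick" packing of polygonal cells on the
#' initial canvas: rows of cells whose vertical walls are offset by half
#' a pitch between adjacent rows (three-way wall junctions, as in real
#' epidermis), with jittered wall positions.  Boundary cell edges follow
#' the mesh outline exactly, so the cells tile the canvas.
#'
#' @param canvas a \code{leaf_canvas}
#' @param variant a \code{\link{model_variant}}
#' @param n_cu cells per row (even rows)
#' @param n_cv number of rows
#' @param jitter wall-position jitter as a fraction of the cell pitch
#' @param mid_half_width half-width (um) of the midline region used for
#'   the lineage-inherited region label
#' @param presplit logical; divide every packing cell once by the noisy
#'   shortest-wall rule during setup, so the initial tissue has the
#'   division-generated wall geometry and topology of real primordium
#'   cells rather than the uniform topology of the raw packing
#' @return tissue state environment
#' @export
init_tissue <- function(canvas, variant, n_cu = 7, n_cv = 16,
                        jitter = 0.2, mid_half_width = 16,
                        presplit = TRUE) {
  tis <- new.env(parent = emptyenv())
  tis$cv <- canvas
  tis$n_vert <- 0L
  tis$vt_elem <- integer(0)
  tis$vt_b <- matrix(0, 0, 3)
  tis$vt_boundary <- logical(0)
  tis$vert_inc <- list()
  tis$cells <- list()
  tis$alive <- logical(0)
  tis$region <- character(0)
  tis$layer <- character(0)
  tis$lineage <- integer(0)
  tis$parent <- integer(0)
  tis$birth <- numeric(0)
  tis$target <- numeric(0)
  tis$competent <- logical(0)
  tis$next_lineage <- 1L
  tis$spaces <- list()
  tis$space_birth <- numeric(0)
  tis$space_r <- numeric(0)
  tis$events <- list()
  tis$elem_cell <- rep(NA_integer_, nrow(canvas$elements))

  n_v <- canvas$n_v
  du <- 2 / n_cu
  vrow <- seq(0, 1, length.out = n_cv + 1)
  # vertical-wall u positions per cell row (offset alternating rows)
  cuts <- lapply(seq_len(n_cv) - 1L, function(j) {
    if (j %% 2 == 0) seq(-1, 1, by = du)
    else c(-1, seq(-1 + du / 2, 1 - du / 2, by = du), 1)
  })

  # vertex grid: one vertex per (row boundary, cut) for cuts of both
  # adjacent rows; keys "j|u" deduplicated
  vert_key <- new.env(parent = emptyenv())
  pending_u <- list(); pending_v <- list(); pending_bnd <- list()
  register <- function(j, u) {
    key <- sprintf("%d|%.10f", j, u)
    if (!is.null(vert_key[[key]])) return(vert_key[[key]])
    id <- length(pending_u) + 1L
    vb <- vrow[j + 1L]
    uu <- u; vvj <- vb
    on_side <- abs(abs(u) - 1) < 1e-9
    on_cap <- j == 0L || j == n_cv
    # jitter interior vertices only, so outline vertices stay ordered
    # with the mesh-boundary refinement nodes
    if (!on_side && !on_cap) {
      uu <- u + stats::runif(1, -jitter, jitter) * du
      vvj <- vb + stats::runif(1, -jitter, jitter) / n_cv
    }
    uu <- pmin(pmax(uu, -1), 1)
    vvj <- pmin(pmax(vvj, 0), 1)
    pending_u[[id]] <<- uu
    pending_v[[id]] <<- vvj
    pending_bnd[[id]] <<- on_side || on_cap
    vert_key[[key]] <- id
    id
  }
  # register all cut vertices (row boundaries carry the cuts of both rows)
  for (j in 0:n_cv) {
    below <- if (j > 0) cuts[[j]] else numeric(0)
    above <- if (j < n_cv) cuts[[j + 1L]] else numeric(0)
    for (u in sort(unique(c(below, above)))) register(j, u)
  }
  # refinement vertices on the outline at mesh boundary nodes
  side_ref <- new.env(parent = emptyenv())  # "s|j_mesh" -> id
  for (s in c(-1, 1)) for (jm in 1:(n_v - 1)) {
    vmesh <- jm / n_v
    id <- length(pending_u) + 1L
    pending_u[[id]] <- s; pending_v[[id]] <- vmesh; pending_bnd[[id]] <- TRUE
    side_ref[[sprintf("%d|%d", s, jm)]] <- id
  }
  cap_ref <- new.env(parent = emptyenv())   # "j(0/1)|i_mesh" -> id
  for (capv in c(0, 1)) for (im in 1:(canvas$n_u - 1)) {
    umesh <- -1 + 2 * im / canvas$n_u
    id <- length(pending_u) + 1L
    pending_u[[id]] <- umesh; pending_v[[id]] <- capv; pending_bnd[[id]] <- TRUE
    cap_ref[[sprintf("%g|%d", capv, im)]] <- id
  }

  uu <- unlist(pending_u); vvp <- unlist(pending_v)
  anch <- param_to_anchor(canvas, uu, vvp)
  ids <- add_vertices(tis, anch)
  tis$vt_boundary <- unlist(pending_bnd)
  vert_u <- uu; vert_v <- vvp

  get_id <- function(j, u) vert_key[[sprintf("%d|%.10f", j, u)]]

  # vertices along a row boundary j with cut-u in [ua, ub] (closed),
  # ordered by u
  boundary_span <- function(j, ua, ub) {
    us <- sort(unique(c(if (j > 0) cuts[[j]] else numeric(0),
                        if (j < n_cv) cuts[[j + 1L]] else numeric(0))))
    us <- us[us >= ua - 1e-9 & us <= ub + 1e-9]
    vapply(us, function(u) get_id(j, u), integer(1))
  }
  # refinement ids along a side wall u = s between row boundaries j and j+1
  side_span <- function(s, j) {
    lo <- vrow[j + 1L]; hi <- vrow[j + 2L]
    jms <- seq_len(n_v - 1)
    jms <- jms[jms / n_v > lo + 1e-9 & jms / n_v < hi - 1e-9]
    out <- vapply(jms, function(jm) side_ref[[sprintf("%d|%d", s, jm)]],
                  integer(1))
    if (s > 0) out else out  # ordered by increasing v
  }
  cap_span <- function(capv, ua, ub) {
    ims <- seq_len(canvas$n_u - 1)
    um <- -1 + 2 * ims / canvas$n_u
    sel <- um > ua + 1e-9 & um < ub - 1e-9
    vapply(ims[sel], function(im) cap_ref[[sprintf("%g|%d", capv, im)]],
           integer(1))
  }

  # assemble cells row by row
  for (j0 in seq_len(n_cv)) {
    cu <- cuts[[j0]]
    for (k in seq_len(length(cu) - 1L)) {
      ua <- cu[k]; ub <- cu[k + 1L]
      bot <- boundary_span(j0 - 1L, ua, ub)
      top <- boundary_span(j0, ua, ub)
      if (j0 == 1L) {  # splice base-cap refinement nodes between cuts
        ins <- cap_span(0, ua, ub)
        bot2 <- integer(0)
        for (q in seq_along(bot)) {
          bot2 <- c(bot2, bot[q])
          if (q < length(bot)) {
            u1 <- vert_u[bot[q]]; u2 <- vert_u[bot[q + 1L]]
            mid_ins <- ins[vert_u[ins] > min(u1, u2) & vert_u[ins] < max(u1, u2)]
            bot2 <- c(bot2, mid_ins[order(vert_u[mid_ins])])
          }
        }
        bot <- bot2
      }
      if (j0 == n_cv) {
        ins <- cap_span(1, ua, ub)
        top2 <- integer(0)
        for (q in seq_along(top)) {
          top2 <- c(top2, top[q])
          if (q < length(top)) {
            u1 <- vert_u[top[q]]; u2 <- vert_u[top[q + 1L]]
            mid_ins <- ins[vert_u[ins] > min(u1, u2) & vert_u[ins] < max(u1, u2)]
            top2 <- c(top2, mid_ins[order(vert_u[mid_ins])])
          }
        }
        top <- top2
      }
      right <- if (abs(ub - 1) < 1e-9) side_span(1, j0 - 1L) else integer(0)
      left <- if (abs(ua + 1) < 1e-9) side_span(-1, j0 - 1L) else integer(0)
      cyc <- c(bot, right, rev(top), rev(left))
      cyc <- cyc[!duplicated(cyc)]
      cid <- length(tis$cells) + 1L
      tis$cells[[cid]] <- cyc
      tis$alive[cid] <- TRUE
      tis$lineage[cid] <- tis$next_lineage
      tis$next_lineage <- tis$next_lineage + 1L
      tis$parent[cid] <- NA_integer_
      tis$birth[cid] <- NA_real_
      tis$target[cid] <- NA_real_
      tis$competent[cid] <- FALSE
      add_incidence(tis, cyc, cid)
    }
  }
  tis$layer <- rep(variant$layer, length(tis$cells))
  refresh_positions(tis)
  cen <- cell_centroids(tis)
  # midline stripe of absolute half-width mid_half_width, capped at half
  # the local leaf half-width so the narrow tip is not engulfed
  local_hw <- halfwidth_profile(canvas$geom, cen[, 2] / canvas$geom$length)
  tis$region <- ifelse(abs(cen[, 1]) <= pmin(mid_half_width, 0.5 * local_hw),
                       "midline", "lamina")
  # orientation check: all cycles counterclockwise
  ar <- cell_areas(tis)
  stopifnot(all(ar[tis$alive] > 0))
  # element -> covering cell (approximate by unjittered grid; exact enough
  # for the cell-size growth feedback, which is smooth in space)
  ec <- element_centroids(canvas)
  ep <- cbind(u = ec[, 1] / pmax(halfwidth_profile(canvas$geom,
                                                   ec[, 2] / canvas$geom$length),
                                 1e-9),
              v = ec[, 2] / canvas$geom$length)
  row_idx <- pmin(pmax(findInterval(ep[, "v"], vrow, rightmost.closed = TRUE),
                       1L), n_cv)
  tis$elem_cell <- vapply(seq_len(nrow(ep)), function(e) {
    j0 <- row_idx[e]
    cu <- cuts[[j0]]
    k <- pmin(pmax(findInterval(ep[e, "u"], cu, rightmost.closed = TRUE), 1L),
              length(cu) - 1L)
    # cell index: cells were appended row by row
    prior <- if (j0 > 1)
      sum(vapply(cuts[seq_len(j0 - 1L)], function(z) length(z) - 1L, integer(1)))
    else 0L
    as.integer(prior + k)
  }, integer(1))
  if (presplit) {
    dp0 <- division_params(variant$layer)
    for (cid in which(tis$alive))
      divide_cell(tis, cid, NA_real_, function(cen, region) dp0$a_min, dp0)
    tis$events <- list()
    tis$layer <- rep(variant$layer, length(tis$cells))
    refresh_positions(tis)
    cen2 <- cell_centroids(tis)
    yy <- ifelse(is.na(cen2[, 2]), 0, cen2[, 2])
    lhw2 <- halfwidth_profile(canvas$geom, yy / canvas$geom$length)
    tis$region <- ifelse(!tis$alive, tis$region,
                         ifelse(abs(cen2[, 1]) <= pmin(mid_half_width, 0.5 * lhw2),
                                "midline", "lamina"))
  }
  tis
}
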
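#' Default primordium geometry
#'
#' Geometry of the initial leaf primordium at the start of the simulated
#' period (87 h after initiation): a rectangular petiole stub capped by a
#' smooth lamina bump.  All lengths in micrometres.  The dimensions are
#' calibration inputs: the published models show the initial canvas only
#' graphically, so the defaults here were fixed once against the printed
#' width anchors of the study system (a primordium on the 0.1 mm width
#' scale growing to a ~3 mm wide mature lamina).
#'
#' @param length total proximodistal length of the primordium (um)
#' @param half_width_lamina maximal mediolateral half-width (um)
#' @param half_width_petiole half-width of the petiole stub (um)
#' @param half_width_tip half-width retained at the distal tip (um);
#'   keeping this positive preserves mesh quality near the tip
#' @param plb_frac position of the petiole-lamina boundary as a fraction
#'   of total length
#' @param peak_frac position of the widest point as a fraction of the
#'   lamina length (distal of the petiole-lamina boundary)
#' @param n_u,n_v number of quad columns/rows of the structured mesh; the
#'   element count is \code{2 * n_u * n_v} (default 3000 elements)
#' @return a list of class \code{"leaf_geometry"}
#' @export
leaf_geometry <- function(length = 310, half_width_lamina = 46,
                          half_width_petiole = 23, half_width_tip = 12,
                          plb_frac = 0.2, peak_frac = 0.45,
                          n_u = 30, n_v = 50) {
  stopifnot(length > 0, half_width_lamina > 0, half_width_petiole > 0,
            half_width_tip > 0, plb_frac > 0, plb_frac < 1,
            peak_frac > 0, peak_frac < 1, n_u >= 4, n_v >= 4)
  if (n_u %% 2 != 0)
    stop("n_u must be even so that a midline node column exists")
  structure(list(length = length, half_width_lamina = half_width_lamina,
                 half_width_petiole = half_width_petiole,
                 half_width_tip = half_width_tip, plb_frac = plb_frac,
                 peak_frac = peak_frac, n_u = n_u, n_v = n_v),
            class = "leaf_geometry")
}

# half-width profile of the primordium outline as a function of the
# normalized proximodistal coordinate v in [0, 1]
halfwidth_profile <- function(geom, v) {
  w <- numeric(length(v))
  vp <- geom$plb_frac
  # snapped peak so the widest point falls exactly on a mesh row
  xi_pk <- geom$peak_frac
  pet <- v <= vp
  w[pet] <- geom$half_width_petiole
  xi <- (v[!pet] - vp) / (1 - vp)
  up <- xi < xi_pk
  wl <- numeric(length(xi))
  wl[up] <- geom$half_width_petiole +
    (geom$half_width_lamina - geom$half_width_petiole) *
    sin((pi / 2) * xi[up] / xi_pk)^2
  wl[!up] <- geom$half_width_lamina -
    (geom$half_width_lamina - geom$half_width_tip) *
    sin((pi / 2) * (xi[!up] - xi_pk) / (1 - xi_pk))^2
  w[!pet] <- wl
  w
}

#' Build the initial triangulated canvas
#'
#' Constructs a structured triangulation of the primordium outline.  Nodes
#' are laid out on a parameter grid (u, v) with u in [-1, 1] mediolateral
#' and v in [0, 1] proximodistal, mapped to x = u * halfwidth(y),
#' y = v * length.  The mesh carries its parameter coordinates for the
#' lifetime of the simulation (material coordinates); the petiole-lamina
#' boundary is anchored to a node row and deforms with the tissue.
#'
#' @param geom a \code{\link{leaf_geometry}} (or NULL for the default)
#' @return an object of class \code{"leaf_canvas"}: nodes (n x 2 um),
#'   elements (m x 3 node indices, counterclockwise), parameter
#'   coordinates, boundary/midline/base/plb node index sets, and a copy of
#'   the initial node positions
#' @export
build_initial_canvas <- function(geom = leaf_geometry()) {
  if (is.null(geom)) geom <- leaf_geometry()
  stopifnot(inherits(geom, "leaf_geometry"))
  n_u <- geom$n_u; n_v <- geom$n_v
  # align the plb and the widest row to mesh rows
  j_plb <- max(1L, round(geom$plb_frac * n_v))
  geom$plb_frac <- j_plb / n_v
  xi_pk_row <- round(geom$peak_frac * (n_v - j_plb))
  geom$peak_frac <- max(1, xi_pk_row) / (n_v - j_plb)

  u <- seq(-1, 1, length.out = n_u + 1)
  v <- seq(0, 1, length.out = n_v + 1)
  uu <- rep(u, times = n_v + 1)
  vv <- rep(v, each = n_u + 1)
  y <- vv * geom$length
  x <- uu * halfwidth_profile(geom, vv)
  nodes <- cbind(x = x, y = y)

  nid <- function(i, j) j * (n_u + 1L) + i + 1L  # i in 0..n_u, j in 0..n_v
  # two triangles per quad; diagonal mirrored about the midline
  el <- matrix(0L, nrow = 2L * n_u * n_v, ncol = 3L)
  k <- 0L
  for (j in 0:(n_v - 1L)) {
    for (i in 0:(n_u - 1L)) {
      a <- nid(i, j); b <- nid(i + 1L, j)
      c <- nid(i + 1L, j + 1L); d <- nid(i, j + 1L)
      if (i < n_u / 2) {   # diagonal a-c
        el[k + 1L, ] <- c(a, b, c); el[k + 2L, ] <- c(a, c, d)
      } else {             # diagonal b-d
        el[k + 1L, ] <- c(a, b, d); el[k + 2L, ] <- c(b, c, d)
      }
      k <- k + 2L
    }
  }
  cv <- structure(list(
    nodes = nodes, elements = el,
    param = cbind(u = uu, v = vv),
    geom = geom,
    n_u = n_u, n_v = n_v,
    j_plb = j_plb,
    base_nodes = nid(0:n_u, 0L),
    plb_nodes = nid(0:n_u, j_plb),
    midline_nodes = nid(n_u / 2L, 0:n_v),
    nodes0 = nodes
  ), class = "leaf_canvas")
  ar <- element_areas(cv)
  if (any(ar <= 0))
    stop("degenerate primordium outline: triangulation has non-positive elements")
  cv
}

#' Signed areas of all mesh elements
#' @param canvas a \code{leaf_canvas}
#' @param nodes optional replacement node coordinates
#' @return numeric vector of element areas (um^2)
#' @export
element_areas <- function(canvas, nodes = canvas$nodes) {
  el <- canvas$elements
  p1 <- nodes[el[, 1], , drop = FALSE]
  p2 <- nodes[el[, 2], , drop = FALSE]
  p3 <- nodes[el[, 3], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

# element centroids
element_centroids <- function(canvas, nodes = canvas$nodes) {
  el <- canvas$elements
  (nodes[el[, 1], , drop = FALSE] + nodes[el[, 2], , drop = FALSE] +
     nodes[el[, 3], , drop = FALSE]) / 3
}

#' Measure leaf-level geometry
#'
#' @param canvas a \code{leaf_canvas}
#' @return list with \code{width_mm} (maximal mediolateral extent),
#'   \code{area_mm2} (summed element areas) and \code{length_mm}
#' @export
measure_leaf <- function(canvas) {
  list(width_mm = (max(canvas$nodes[, 1]) - min(canvas$nodes[, 1])) / 1000,
       area_mm2 = sum(element_areas(canvas)) / 1e6,
       length_mm = (max(canvas$nodes[, 2]) - min(canvas$nodes[, 2])) / 1000)
}

# cumulative arc length along the (deformed) midline node column, indexed
# by the parameter coordinate v of its nodes; returns an interpolator
# v -> signed distance from the petiole-lamina boundary (um, positive
# distal)
midline_arclength <- function(canvas) {
  mid <- canvas$midline_nodes
  p <- canvas$nodes[mid, , drop = FALSE]
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  s <- c(0, cumsum(seg))
  vmid <- canvas$param[mid, "v"]
  s_plb <- s[canvas$j_plb + 1L]
  function(vq) {
    stats::approx(vmid, s - s_plb, xout = pmin(pmax(vq, 0), 1), rule = 2)$y
  }
}

#' Proximodistal distance to the petiole-lamina boundary
#'
#' Distance measured as arc length along the deformed midline between the
#' anchored boundary row and the material row of the query points
#' (positive distal, negative in the petiole).
#'
#' @param canvas a \code{leaf_canvas}
#' @param v parameter coordinate(s) of the query points (material
#'   proximodistal coordinate in [0, 1])
#' @return distances in micrometres
#' @export
dist_to_plb <- function(canvas, v) midline_arclength(canvas)(v)

#' @export
print.leaf_canvas <- function(x, ...) {
  m <- measure_leaf(x)
  cat("leaf canvas:", nrow(x$nodes), "nodes,", nrow(x$elements), "elements\n")
  cat(sprintf("  width %.3f mm, length %.3f mm, area %.4f mm^2\n",
              m$width_mm, m$length_mm, m$area_mm2))
  invisible(x)
}
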
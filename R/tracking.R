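#' Tracking dataset
#'
#' Common container for tracked-vertex data, whether exported from a
#' simulation or generated parametrically (and matching the layout of
#' vertex-click tracking tables from live imaging): per-timepoint vertex
#' positions, cell polygons as vertex-id cycles, lineage links, region
#' labels and the petiole-lamina boundary position.
#'
#' @param timepoints strictly increasing times (h)
#' @param vertices list (per timepoint) of data.frames with
#'   \code{vertex_id}, \code{x}, \code{y} (um)
#' @param cells list (per timepoint) of data.frames with
#'   \code{cell_id}, \code{lineage_id}, \code{region}, \code{layer},
#'   \code{vertices} (space-separated ordered vertex ids)
#' @param lineage data.frame with \code{parent}, \code{daughter1},
#'   \code{daughter2}, \code{time} (one row per division)
#' @param plb_position proximodistal position of the petiole-lamina
#'   boundary per timepoint (um, along the midline axis)
#' @param midline_axis unit 2-vector of the proximodistal axis
#' @param metadata list (sampling interval, noise level, source, seed)
#' @return object of class \code{"tracking_dataset"}
#' @export
tracking_dataset <- function(timepoints, vertices, cells, lineage,
                             plb_position = rep(0, length(timepoints)),
                             midline_axis = c(0, 1), metadata = list()) {
  stopifnot(length(timepoints) >= 1, all(diff(timepoints) > 0),
            length(vertices) == length(timepoints),
            length(cells) == length(timepoints))
  structure(list(timepoints = timepoints, vertices = vertices,
                 cells = cells, lineage = lineage,
                 plb_position = rep_len(plb_position, length(timepoints)),
                 midline_axis = midline_axis / sqrt(sum(midline_axis^2)),
                 metadata = metadata),
            class = "tracking_dataset")
}

#' @export
print.tracking_dataset <- function(x, ...) {
  cat("tracking_dataset:", length(x$timepoints), "timepoints",
      sprintf("(%g-%g h),", min(x$timepoints), max(x$timepoints)),
      nrow(x$cells[[1]]), "cells at first timepoint,",
      nrow(x$lineage), "divisions\n")
  invisible(x)
}

ds_tp_index <- function(ds, t) {
  i <- which(abs(ds$timepoints - t) < 1e-6)
  if (!length(i)) stop("no timepoint at t = ", t)
  i[1]
}

parse_cycle <- function(s) as.integer(strsplit(s, " ", fixed = TRUE)[[1]])

# polygon (positions) of one cell at one timepoint
ds_polygon <- function(ds, tp, row) {
  vt <- ds$vertices[[tp]]
  ids <- parse_cycle(ds$cells[[tp]]$vertices[row])
  m <- match(ids, vt$vertex_id)
  cbind(vt$x[m], vt$y[m])
}

ds_areas <- function(ds, tp) {
  vapply(seq_len(nrow(ds$cells[[tp]])), function(r)
    polygon_area(ds_polygon(ds, tp, r)), numeric(1))
}

# lineage ids of all descendants of `id` alive at timepoint tp
clone_members <- function(ds, id, tp) {
  present <- ds$cells[[tp]]$lineage_id
  if (id %in% present) return(id)
  kids <- ds$lineage[ds$lineage$parent == id, c("daughter1", "daughter2")]
  if (!nrow(kids)) return(integer(0))
  unlist(lapply(unlist(kids), clone_members, ds = ds, tp = tp))
}

#' Clonal areal growth rate
#'
#' Relative elemental growth rate \code{ln(A(t2)/A(t1)) / (t2 - t1)} of
#' a cell, where the area at t2 is the area of the clone (all
#' descendants) if the cell divided in the interval.
#'
#' @param ds a \code{\link{tracking_dataset}}
#' @param lineage_id cell identity at t1
#' @param t1,t2 timepoints present in the dataset (t2 > t1)
#' @return rate in 1/h (NA if the lineage is broken)
#' @export
areal_growth_rate <- function(ds, lineage_id, t1, t2) {
  stopifnot(t2 > t1)
  i1 <- ds_tp_index(ds, t1); i2 <- ds_tp_index(ds, t2)
  r1 <- which(ds$cells[[i1]]$lineage_id == lineage_id)
  if (!length(r1)) return(NA_real_)
  a1 <- polygon_area(ds_polygon(ds, i1, r1))
  members <- clone_members(ds, lineage_id, i2)
  if (!length(members)) return(NA_real_)
  rows2 <- match(members, ds$cells[[i2]]$lineage_id)
  if (anyNA(rows2)) return(NA_real_)
  a2 <- sum(vapply(rows2, function(r) polygon_area(ds_polygon(ds, i2, r)),
                   numeric(1)))
  log(a2 / a1) / (t2 - t1)
}

#' Directional growth rates of a tracked cell
#'
#' Fits the least-squares affine map between the cell's (clone's)
#' tracked vertices at two timepoints and projects the log right-stretch
#' tensor on the midline axis and its perpendicular, so that
#' parallel + perpendicular = areal exactly and rigid motions give zero.
#'
#' @inheritParams areal_growth_rate
#' @param midline_axis unit axis (default: dataset metadata)
#' @return list with \code{parallel}, \code{perpendicular},
#'   \code{areal} (1/h), or NULL if fewer than three non-collinear
#'   shared vertices exist
#' @export
directional_growth_rates <- function(ds, lineage_id, t1, t2,
                                     midline_axis = ds$midline_axis) {
  stopifnot(t2 > t1)
  i1 <- ds_tp_index(ds, t1); i2 <- ds_tp_index(ds, t2)
  r1 <- which(ds$cells[[i1]]$lineage_id == lineage_id)
  if (!length(r1)) return(NULL)
  ids1 <- parse_cycle(ds$cells[[i1]]$vertices[r1])
  vt1 <- ds$vertices[[i1]]; vt2 <- ds$vertices[[i2]]
  shared <- intersect(ids1, vt2$vertex_id)
  if (length(shared) < 3) return(NULL)
  P1 <- cbind(vt1$x[match(shared, vt1$vertex_id)],
              vt1$y[match(shared, vt1$vertex_id)])
  P2 <- cbind(vt2$x[match(shared, vt2$vertex_id)],
              vt2$y[match(shared, vt2$vertex_id)])
  X <- cbind(1, P1)
  if (qr(X)$rank < 3) return(NULL)   # collinear vertices
  cf <- qr.solve(X, P2)              # rows: intercept, x, y
  Fel <- list(f11 = cf[2, 1], f12 = cf[3, 1],
              f21 = cf[2, 2], f22 = cf[3, 2])
  ax <- matrix(midline_axis / sqrt(sum(midline_axis^2)), 1, 2)
  rates <- tensor_growth_rates(Fel, ax, t2 - t1)
  list(parallel = rates$parallel, perpendicular = rates$perpendicular,
       areal = rates$areal)
}

# division records: one row per division with mother area at execution
# (mother's area at the last timepoint it is present), position,
# distance to the plb, region and cycle duration
division_records <- function(ds) {
  if (!nrow(ds$lineage)) return(
    data.frame(parent = integer(0), time = numeric(0), area = numeric(0),
               dist_plb = numeric(0), region = character(0),
               duration = numeric(0)))
  ax <- ds$midline_axis
  rows <- lapply(seq_len(nrow(ds$lineage)), function(i) {
    ln <- ds$lineage[i, ]
    tps <- which(vapply(ds$cells, function(ct) ln$parent %in% ct$lineage_id,
                        logical(1)))
    if (!length(tps)) return(NULL)
    tp <- max(tps)
    r <- which(ds$cells[[tp]]$lineage_id == ln$parent)
    P <- ds_polygon(ds, tp, r)
    cen <- polygon_centroid(P)
    # birth time: parent's own creation (division of grandparent) if
    # recorded, else first appearance
    gp <- which(ds$lineage$daughter1 == ln$parent |
                  ds$lineage$daughter2 == ln$parent)
    birth <- if (length(gp)) ds$lineage$time[gp[1]] else
      ds$timepoints[min(tps)]
    data.frame(parent = ln$parent, time = ln$time,
               area = polygon_area(P),
               dist_plb = sum(cen * ax) - ds$plb_position[tp],
               region = ds$cells[[tp]]$region[r],
               duration = ln$time - birth)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Division statistics by stratum
#'
#' Means with 1.96 x standard-error ranges of cell area at division
#' execution and of cell-cycle duration, stratified as in the tracked
#' data: midline, proximal lamina (distance to the petiole-lamina
#' boundary in [0, 150) um) and distal lamina (>= 150 um).
#'
#' @param ds a \code{\link{tracking_dataset}}
#' @param window time window (t_a, t_b] of division times to include
#' @param proximal_band distance splitting the lamina strata (um)
#' @return data.frame with one row per stratum: n, mean area, 1.96 SEM,
#'   mean duration, 1.96 SEM
#' @export
division_statistics <- function(ds, window = range(ds$timepoints),
                                proximal_band = 150) {
  rec <- division_records(ds)
  rec <- rec[rec$time > window[1] & rec$time <= window[2], , drop = FALSE]
  strat <- ifelse(rec$region == "midline", "midline",
                  ifelse(rec$dist_plb < proximal_band,
                         "lamina_proximal", "lamina_distal"))
  out <- lapply(c("lamina_proximal", "lamina_distal", "midline"),
                function(sname) {
    r <- rec[strat == sname, , drop = FALSE]
    n <- nrow(r)
    if (n == 0) return(data.frame(stratum = sname, n = 0,
                                  mean_area = NA, ci_area = NA,
                                  mean_duration = NA, ci_duration = NA))
    data.frame(stratum = sname, n = n, mean_area = mean(r$area),
               ci_area = 1.96 * stats::sd(r$area) / sqrt(n),
               mean_duration = mean(r$duration),
               ci_duration = 1.96 * stats::sd(r$duration) / sqrt(n))
  })
  do.call(rbind, out)
}

#' Competence classification over a tracking interval
#'
#' Classifies each cell present at the interval start by its division
#' fate: \code{divides_in_interval}, \code{divides_later} (divides after
#' the interval, within the tracked period) or \code{never_divides}
#' (no recorded division; conservatively includes lineages truncated by
#' the end of the dataset, flagged in \code{truncated}).
#'
#' @param ds a \code{\link{tracking_dataset}}
#' @param interval c(t_a, t_b)
#' @return data.frame with \code{lineage_id}, \code{class},
#'   \code{truncated}
#' @export
competence_classification <- function(ds, interval) {
  i1 <- ds_tp_index(ds, interval[1])
  ids <- ds$cells[[i1]]$lineage_id
  t_end <- max(ds$timepoints)
  cls <- vapply(ids, function(id) {
    div <- ds$lineage$time[ds$lineage$parent == id]
    if (length(div) && div[1] <= interval[2]) "divides_in_interval"
    else if (length(div)) "divides_later"
    else "never_divides"
  }, character(1))
  data.frame(lineage_id = ids, class = cls,
             truncated = cls == "never_divides" & t_end > interval[2])
}

# neighbour counts from a list of vertex-id cycles; boundary polygons
# (with an unshared edge) are excluded (NA)
neighbour_counts <- function(cycles) {
  edge_owner <- list()
  key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  for (i in seq_along(cycles)) {
    cyc <- cycles[[i]]
    n <- length(cyc)
    for (k in seq_len(n)) {
      ky <- key(cyc[k], cyc[k %% n + 1])
      edge_owner[[ky]] <- c(edge_owner[[ky]], i)
    }
  }
  nb <- vector("list", length(cycles))
  boundary <- logical(length(cycles))
  for (ky in names(edge_owner)) {
    ow <- edge_owner[[ky]]
    if (length(ow) == 1) boundary[ow] <- TRUE
    else if (length(ow) == 2) {
      nb[[ow[1]]] <- c(nb[[ow[1]]], ow[2])
      nb[[ow[2]]] <- c(nb[[ow[2]]], ow[1])
    }
  }
  out <- vapply(nb, function(z) length(unique(z)), integer(1))
  out[boundary] <- NA_integer_
  out
}

#' Polygon-topology distribution
#'
#' Frequency of n-sided cells (n = number of distinct edge-sharing
#' neighbours), over interior cells of a tracking-dataset timepoint or a
#' \code{leaf_sim} snapshot.  Cells touching the tissue boundary are
#' excluded.
#'
#' @param x a \code{tracking_dataset} or \code{leaf_sim}
#' @param t timepoint (dataset) or snapshot index (simulation); default
#'   last
#' @param n_range neighbour numbers to tabulate
#' @return named numeric vector of frequencies summing to 1
#' @export
topology_distribution <- function(x, t = NULL, n_range = 3:12) {
  cycles <- if (inherits(x, "tracking_dataset")) {
    tp <- if (is.null(t)) length(x$timepoints) else ds_tp_index(x, t)
    lapply(x$cells[[tp]]$vertices, parse_cycle)
  } else if (inherits(x, "leaf_sim")) {
    s <- x$snapshots[[if (is.null(t)) length(x$snapshots) else t]]
    c(s$cells, s$spaces)
  } else stop("unsupported input")
  nc <- neighbour_counts(cycles)
  if (inherits(x, "leaf_sim")) {
    s <- x$snapshots[[if (is.null(t)) length(x$snapshots) else t]]
    nc <- nc[seq_along(s$cells)]   # spaces contribute edges, not counts
  }
  nc <- nc[!is.na(nc)]
  freq <- vapply(n_range, function(n) mean(nc == n), numeric(1))
  names(freq) <- n_range
  freq / sum(freq)
}

#' Write / read a tracking dataset as a CSV trio
#'
#' \code{vertices.csv} (time, vertex_id, x, y), \code{cells.csv} (time,
#' cell_id, lineage_id, region, layer, vertices) and \code{lineage.csv}
#' (parent, daughter1, daughter2, time), with a versioned header line
#' carrying timepoints, plb positions, the midline axis and metadata.
#'
#' @param ds a \code{\link{tracking_dataset}}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly (write) or the dataset (read)
#' @export
write_tracking_csv <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# leafdyn tracking v1 | timepoints=%s | plb=%s | axis=%s",
                 paste(ds$timepoints, collapse = ","),
                 paste(signif(ds$plb_position, 8), collapse = ","),
                 paste(signif(ds$midline_axis, 8), collapse = ","))
  vt <- do.call(rbind, lapply(seq_along(ds$timepoints), function(i)
    cbind(time = ds$timepoints[i], ds$vertices[[i]])))
  ct <- do.call(rbind, lapply(seq_along(ds$timepoints), function(i)
    cbind(time = ds$timepoints[i], ds$cells[[i]])))
  for (f in c("vertices", "cells")) {
    path <- file.path(dir, paste0(f, ".csv"))
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(
      if (f == "vertices") vt else ct, path, sep = ",",
      row.names = FALSE, append = TRUE, qmethod = "double"))
  }
  utils::write.csv(ds$lineage, file.path(dir, "lineage.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_tracking_csv
#' @export
read_tracking_csv <- function(dir) {
  hdr <- readLines(file.path(dir, "vertices.csv"), n = 1)
  parse_field <- function(name) {
    m <- regmatches(hdr, regexpr(paste0(name, "=[^|]+"), hdr))
    as.numeric(strsplit(sub(paste0(name, "="), "", m), ",")[[1]])
  }
  tps <- parse_field("timepoints")
  plb <- parse_field("plb")
  axis <- parse_field("axis")
  vt <- utils::read.csv(file.path(dir, "vertices.csv"), skip = 1)
  ct <- utils::read.csv(file.path(dir, "cells.csv"), skip = 1,
                        colClasses = c(vertices = "character"))
  ln <- utils::read.csv(file.path(dir, "lineage.csv"))
  tracking_dataset(
    timepoints = tps,
    vertices = lapply(tps, function(t) {
      d <- vt[abs(vt$time - t) < 1e-6, c("vertex_id", "x", "y")]
      rownames(d) <- NULL; d
    }),
    cells = lapply(tps, function(t) {
      d <- ct[abs(ct$time - t) < 1e-6,
              c("cell_id", "lineage_id", "region", "layer", "vertices")]
      rownames(d) <- NULL; d
    }),
    lineage = ln, plb_position = plb, midline_axis = axis,
    metadata = list(source = "csv"))
}
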
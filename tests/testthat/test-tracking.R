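# hand-built dataset: one square cell that doubles in area, then divides
toy_dataset <- function() {
  sq <- function(s, x0 = 0) data.frame(
    vertex_id = 1:4,
    x = x0 + c(0, s, s, 0), y = c(0, 0, s, s))
  cells_t <- function(ids, cycles, region = "lamina") data.frame(
    cell_id = ids, lineage_id = ids, region = region, layer = "epidermis",
    vertices = cycles)
  v3 <- rbind(sq(20), data.frame(vertex_id = 5:6, x = c(10, 10), y = c(0, 20)))
  tracking_dataset(
    timepoints = c(0, 10, 15),
    vertices = list(sq(10), sq(sqrt(2) * 10), v3),
    cells = list(cells_t(1L, "1 2 3 4"),
                 cells_t(1L, "1 2 3 4"),
                 cells_t(c(2L, 3L), c("1 5 6 4", "5 2 3 6"))),
    lineage = data.frame(parent = 1L, daughter1 = 2L, daughter2 = 3L,
                         time = 12),
    plb_position = c(0, 0, 0))
}

test_that("clonal areal growth rates use the log-ratio with clone areas", {
  ds <- toy_dataset()
  expect_equal(areal_growth_rate(ds, 1, 0, 10), log(2) / 10)
  # across the division the clone area (two daughters) is used
  expect_equal(areal_growth_rate(ds, 1, 0, 15), log(400 / 100) / 15)
  # zero growth
  ds0 <- ds; ds0$vertices[[2]] <- ds0$vertices[[1]]
  expect_equal(areal_growth_rate(ds0, 1, 0, 10), 0)
  # unknown lineage flagged as NA
  expect_true(is.na(areal_growth_rate(ds, 99, 0, 10)))
})

test_that("directional rates decompose stretch on the midline axis", {
  base <- data.frame(vertex_id = 1:4, x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  mk <- function(v2) tracking_dataset(
    timepoints = c(0, 10), vertices = list(base, v2),
    cells = list(data.frame(cell_id = 1L, lineage_id = 1L, region = "lamina",
                            layer = "epidermis", vertices = "1 2 3 4"),
                 data.frame(cell_id = 1L, lineage_id = 1L, region = "lamina",
                            layer = "epidermis", vertices = "1 2 3 4")),
    lineage = data.frame(parent = integer(0), daughter1 = integer(0),
                         daughter2 = integer(0), time = numeric(0)))
  # pure vertical stretch
  d1 <- directional_growth_rates(mk(transform(base, y = 1.5 * y)), 1, 0, 10)
  expect_equal(d1$parallel, log(1.5) / 10, tolerance = 1e-9)
  expect_equal(d1$perpendicular, 0, tolerance = 1e-9)
  # rigid rotation: all rates zero
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- as.data.frame(cbind(base$vertex_id,
                             t(R %*% t(cbind(base$x, base$y)))))
  names(rot) <- c("vertex_id", "x", "y")
  d2 <- directional_growth_rates(mk(rot), 1, 0, 10)
  expect_equal(d2$areal, 0, tolerance = 1e-9)
  expect_equal(d2$parallel, 0, tolerance = 1e-9)
  # simple shear: trace identity
  d3 <- directional_growth_rates(mk(transform(base, x = x + 0.5 * y)),
                                 1, 0, 10)
  expect_equal(d3$parallel + d3$perpendicular, d3$areal, tolerance = 1e-9)
})

test_that("metrics are invariant to rotation plus translation", {
  ds <- toy_dataset()
  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ds2 <- ds
  for (i in seq_along(ds2$vertices)) {
    P <- t(R %*% t(cbind(ds2$vertices[[i]]$x, ds2$vertices[[i]]$y))) +
      matrix(c(31, -17), nrow(ds2$vertices[[i]]), 2, byrow = TRUE)
    ds2$vertices[[i]]$x <- P[, 1]; ds2$vertices[[i]]$y <- P[, 2]
  }
  ds2$midline_axis <- as.numeric(R %*% ds$midline_axis)
  expect_equal(areal_growth_rate(ds2, 1, 0, 10),
               areal_growth_rate(ds, 1, 0, 10), tolerance = 1e-9)
  d_a <- directional_growth_rates(ds, 1, 0, 10)
  d_b <- directional_growth_rates(ds2, 1, 0, 10)
  expect_equal(d_b$parallel, d_a$parallel, tolerance = 1e-9)
  expect_equal(d_b$perpendicular, d_a$perpendicular, tolerance = 1e-9)
})

test_that("division statistics stratify by region and distance bands", {
  ds <- toy_dataset()
  st <- division_statistics(ds)
  pr <- st[st$stratum == "lamina_proximal", ]
  expect_equal(pr$n, 1)
  expect_equal(pr$mean_area, 200)      # mother area at last presence (t = 10)
  # degenerate CI when all executions identical
  expect_true(pr$ci_area == 0 || is.na(pr$ci_area))
  # boundary convention: [0, 150) proximal, [150, Inf) distal
  rec <- data.frame(region = c("lamina", "lamina"), dist_plb = c(149, 151))
  strat <- ifelse(rec$dist_plb < 150, "proximal", "distal")
  expect_identical(strat, c("proximal", "distal"))
})

test_that("competence classes follow division fate within the interval", {
  ds <- toy_dataset()
  cc <- competence_classification(ds, c(0, 15))
  expect_equal(cc$class[cc$lineage_id == 1], "divides_in_interval")
  cc2 <- competence_classification(ds, c(0, 10))
  expect_equal(cc2$class[cc2$lineage_id == 1], "divides_later")
  # daughters never divide within the tracked period -> conservative class
  cc3 <- competence_classification(ds, c(15, 15))
  expect_true(all(cc3$class == "never_divides"))
})

test_that("topology counts edge-sharing neighbours on a hand fixture", {
  # 3 x 3 quad grid: only the centre cell is interior, with 4 neighbours
  vid <- function(i, j) j * 4L + i + 1L
  cyc <- function(i, j) paste(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1),
                              vid(i, j + 1))
  cells <- expand.grid(i = 0:2, j = 0:2)
  vt <- expand.grid(i = 0:3, j = 0:3)
  ds <- tracking_dataset(
    timepoints = 0,
    vertices = list(data.frame(vertex_id = vid(vt$i, vt$j),
                               x = vt$i * 10, y = vt$j * 10)),
    cells = list(data.frame(cell_id = 1:9, lineage_id = 1:9,
                            region = "lamina", layer = "epidermis",
                            vertices = mapply(cyc, cells$i, cells$j))),
    lineage = data.frame(parent = integer(0), daughter1 = integer(0),
                         daughter2 = integer(0), time = numeric(0)))
  tp <- topology_distribution(ds, 0)
  expect_equal(unname(tp["4"]), 1)
  expect_equal(sum(tp), 1)
})

test_that("the CSV trio round-trips a dataset", {
  ds <- toy_dataset()
  dir <- file.path(tempdir(), "leafdyn-csv-test")
  write_tracking_csv(ds, dir)
  ds2 <- read_tracking_csv(dir)
  expect_equal(ds2$timepoints, ds$timepoints)
  expect_equal(ds2$plb_position, ds$plb_position)
  expect_equal(ds2$lineage$parent, ds$lineage$parent)
  for (i in seq_along(ds$timepoints)) {
    expect_equal(ds2$vertices[[i]]$x, ds$vertices[[i]]$x, tolerance = 1e-6)
    expect_identical(ds2$cells[[i]]$vertices, ds$cells[[i]]$vertices)
  }
  expect_equal(areal_growth_rate(ds2, 1, 0, 15),
               areal_growth_rate(ds, 1, 0, 15), tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
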
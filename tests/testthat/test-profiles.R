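test_that("slit profile converts counts to densities bin by bin", {
  box <- slit_box(10, 4, 5)
  beads <- tibble::tibble(
    species = c(rep("B", 6), rep("S", 2), "W"),
    x = c(-4.9, -4.9, -4.9, 0.1, 0.1, 3.6, 0.1, 0.1, 5.5),
    y = 1, z = 1, chain_id = c(rep(0L, 6), -1L, -1L, -1L),
    frozen = c(rep(FALSE, 8), TRUE), vx = 0, vy = 0, vz = 0)
  cfg <- make_config(beads, box)
  pr <- slit_profile(cfg, species = "B", bin_width = 0.25)
  expect_equal(nrow(pr), 40)
  area <- 4 * 5
  # three beads in the first bin, two in the bin holding x = 0.1
  expect_equal(pr$density[pr$x == -4.875], 3 / (0.25 * area))
  expect_equal(pr$density[pr$x == 0.125], 2 / (0.25 * area))
  expect_equal(sum(pr$density > 0), 3)
  # frozen wall beads and other species never enter
  prS <- slit_profile(cfg, species = c("S", "W"), bin_width = 0.25)
  expect_equal(sum(prS$density[prS$species == "S"] > 0), 1)
  expect_equal(sum(prS$density[prS$species == "W"]), 0)
  expect_error(slit_profile(make_config(beads[1, ], bulk_box(10))), "slit")
})

test_that("profile integral recovers the mean per-frame bead count", {
  cfg <- build_slit(5, box = slit_box(6, 8, 8), seed = 9)
  pr <- slit_profile(cfg, species = c("A", "B", "S"), bin_width = 0.2)
  tot <- dplyr::summarise(dplyr::group_by(pr, species),
                          n = sum(density) * 0.2 * 8 * 8)
  expect_equal(tot$n[tot$species == "A"], 25)
  expect_equal(tot$n[tot$species == "B"], 25)
  expect_equal(sum(tot$n), sum(!cfg$frozen))
  # averaging a frame with itself changes nothing
  pr2 <- slit_profile(list(cfg, cfg), species = "B", bin_width = 0.2)
  expect_equal(pr2$density, pr$density[pr$species == "B"])
})

test_that("directional scans resolve planted layers and fold on the right period", {
  box <- bulk_box(10)
  withr::local_seed(41)
  n <- 60
  beads <- tibble::tibble(
    species = "B",
    x = runif(2 * n, 0, 10), y = runif(2 * n, 0, 10),
    z = rep(c(2, 7), each = n) + 0.01,
    chain_id = 0L, frozen = FALSE, vx = 0, vy = 0, vz = 0)
  cfg <- make_config(beads, box)
  pr <- directional_scan(cfg, c(0, 0, 1), bin_width = 0.25)
  expect_equal(nrow(pr), 40)              # one box period, exact tiling
  expect_equal(sum(pr$density > 0), 2)    # two occupied bins only
  expect_equal(layer_count(pr), 2L)
  # oblique scan: period is the shortest projected lattice vector
  pro <- directional_scan(cfg, c(0, 1, 1), bin_width = 0.25)
  nb <- nrow(pro)
  expect_equal(nb * attr(pro, "bin_width"), 10 / sqrt(2), tolerance = 1e-12)
  # every bead is counted exactly once per period
  expect_equal(sum(pro$density) * 1000 / nb, 2 * n)
  expect_error(directional_scan(cfg, c(0, 0, 0)), "non-zero")
})

test_that("uniform random beads give a flat scan at the bulk density", {
  withr::local_seed(7)
  n <- 3000
  beads <- tibble::tibble(
    species = "S", x = runif(n, 0, 10), y = runif(n, 0, 10),
    z = runif(n, 0, 10), chain_id = -1L, frozen = FALSE,
    vx = 0, vy = 0, vz = 0)
  cfg <- make_config(beads, bulk_box(10))
  for (u in list(c(1, 0, 0), c(0, 1, 1), c(1, 2, 3))) {
    pr <- directional_scan(cfg, u, species = "S", bin_width = 0.5)
    expect_equal(mean(pr$density), 3, tolerance = 1e-12)  # exact bookkeeping
  }
})

test_that("slit scans are restricted to the x axis or the periodic plane", {
  cfg <- build_slit(2, box = slit_box(6, 6, 6), seed = 1)
  expect_error(directional_scan(cfg, c(1, 1, 0)), "y-z plane")
  prx <- directional_scan(cfg, c(1, 0, 0))
  prs <- slit_profile(cfg)
  expect_equal(prx$density, prs$density)
  pry <- directional_scan(cfg, c(0, 1, 0))
  expect_equal(nrow(pry), 24)
})

test_that("wall coverage counts core beads per unit wall area", {
  box <- slit_box(10, 4, 5)
  beads <- tibble::tibble(
    species = c(rep("B", 6), "S"),
    x = c(-4.5, -4.2, -4.05, 4.2, 4.9, 0, -4.5),
    y = 1, z = 1, chain_id = 0L, frozen = FALSE, vx = 0, vy = 0, vz = 0)
  cfg <- make_config(beads, box)
  cov <- wall_coverage(cfg)
  expect_equal(cov$rho_c[cov$wall == "lower"], 3 / 20)
  expect_equal(cov$rho_c[cov$wall == "upper"], 2 / 20)
  # a wider adsorbed layer can only add beads; at width = D/2 the two
  # layers meet, so the midplane bead counts toward both walls
  cov2 <- wall_coverage(cfg, width = 5)
  expect_true(all(cov2$rho_c >= cov$rho_c))
  expect_equal(sum(cov2$rho_c) * 20, 7)
  expect_error(wall_coverage(cfg, width = 6), "width")
})

test_that("layer counting is prominence-gated and ignores ripple", {
  t <- seq(0, 1 - 1 / 240, by = 1 / 240)
  expect_equal(layer_count(1 + sin(2 * pi * 3 * t)), 3L)
  expect_equal(layer_count(rep(2, 100)), 0L)
  expect_equal(layer_count(seq(0, 1, length.out = 50)), 0L)
  # ripple far below the prominence gate
  expect_equal(layer_count(1 + 0.02 * sin(2 * pi * 5 * t)), 0L)
  # the same oscillation about zero baseline is fully prominent
  expect_equal(layer_count(0.02 + 0.02 * sin(2 * pi * 5 * t)), 5L)
  expect_error(
    layer_count(slit_profile(build_slit(2, box = slit_box(6, 6, 6), seed = 1),
                             species = c("A", "B"))),
    "single-species")
})
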
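test_that("gyration closed forms: point, pair, translation invariance", {
  expect_equal(gyration(matrix(c(1, 2, 3), 1))$lambda_sq, c(0, 0, 0))
  d <- 2.6
  g <- gyration(rbind(c(0, 0, 0), c(0, d, 0)))
  expect_equal(g$lambda_sq, c(0, 0, d^2 / 4))
  pts <- matrix(rnorm(60), ncol = 3)
  shifted <- sweep(pts, 2, c(5, -3, 11), "+")
  expect_equal(gyration(pts)$lambda_sq, gyration(shifted)$lambda_sq,
               tolerance = 1e-12)
})

test_that("eigenvalues match the closed-form symmetric 3x3 solution", {
  withr::local_seed(12)
  for (i in 1:100) {
    pts <- matrix(rnorm(3 * sample(3:40, 1)), ncol = 3)
    S <- crossprod(sweep(pts, 2, colMeans(pts))) / nrow(pts)
    expect_equal(gyration(pts)$lambda_sq, oracle_eigen_sym3(S),
                 tolerance = 1e-10)
  }
})

test_that("eigen mode is rotation invariant; diagonal mode is not", {
  withr::local_seed(21)
  pts <- rbind(matrix(rnorm(30, sd = 0.2), ncol = 3),
               cbind(rnorm(10, sd = 0.2), rnorm(10, sd = 0.2),
                     seq(-2, 2, length.out = 10)))
  g0 <- gyration(pts)$lambda_sq
  for (i in 1:5) {
    R <- random_rotation()
    expect_equal(gyration(pts %*% t(R))$lambda_sq, g0, tolerance = 1e-10)
  }
  gd <- gyration(pts, mode = "diagonal")$lambda_sq
  R <- random_rotation()
  expect_false(isTRUE(all.equal(gyration(pts %*% t(R),
                                         mode = "diagonal")$lambda_sq, gd)))
  expect_equal(sum(gd), sum(g0))  # trace is basis independent
})

test_that("unwrap restores minimum-image separations across boundaries", {
  box <- bulk_box(25)
  beads <- tibble::tibble(
    species = "B", x = 1, y = c(0.1, 24.9), z = 1,
    chain_id = 0:1, frozen = FALSE, vx = 0, vy = 0, vz = 0)
  cfg <- make_config(beads, box)
  up <- unwrap_aggregate(cfg, 0:1, species = "B")
  expect_equal(abs(diff(up[, 2])), 0.2, tolerance = 1e-12)
  # a compact aggregate away from every boundary is untouched
  mic <- planted_config(plant_micelle(5, center = c(6, 6, 6), seed = 3),
                        bulk_box(12))
  up2 <- unwrap_aggregate(mic, 0:4)
  expect_equal(up2[, 1], mic$x[mic$chain_id %in% 0:4])
  # an aggregate spanning over half the box is flagged
  wide <- tibble::tibble(
    species = "B", x = 1, y = seq(0.2, 24.8, by = 0.8), z = 1,
    chain_id = 0L, frozen = FALSE, vx = 0, vy = 0, vz = 0)
  expect_warning(unwrap_aggregate(make_config(wide, box), 0L, species = "B"),
                 "ambiguous")
})

test_that("gyration of a micelle is invariant to which periodic image hosts it", {
  mic <- plant_micelle(8, core_radius = 1.4, center = c(0.2, 0.1, 11.9),
                       seed = 5)
  cfg <- planted_config(mic, bulk_box(12))  # wrapped across three faces
  up <- unwrap_aggregate(cfg, 0:7)
  g_wrapped <- gyration(up)$lambda_sq
  cfg_c <- planted_config(plant_micelle(8, core_radius = 1.4,
                                        center = c(6, 6, 6), seed = 5),
                          bulk_box(12))
  g_center <- gyration(unwrap_aggregate(cfg_c, 0:7))$lambda_sq
  expect_equal(g_wrapped, g_center, tolerance = 1e-10)
})

test_that("planted spheres scale with exponent 1/3; rods grow only lengthwise", {
  # rigid homogeneous balls: lambda ~ N^(1/3) exactly in the continuum
  sizes <- c(2, 2.5, 3, 3.5, 4, 5)
  tbl <- purrr::map_dfr(sizes, function(r) {
    pts <- lattice_sphere(r, h = 0.4)
    lam <- gyration(pts)$lambda_sq
    tibble::tibble(a_s = nrow(pts), lambda1_sq = lam[1], lambda2_sq = lam[2],
                   lambda3_sq = lam[3], rg_sq = sum(lam))
  })
  fit <- fit_size_exponent(tbl)
  expect_equal(fit$exponent[fit$component == "rg"], 1 / 3, tolerance = 0.02)
  expect_equal(fit$exponent[fit$component == "lambda3"], 1 / 3,
               tolerance = 0.02)

  # planted rods: dominant eigenvalue grows as length^2/12, short axes flat
  lens <- c(4, 6, 8, 12)
  rods <- purrr::map_dfr(lens, function(L) {
    rod <- plant_rod(max(10, round(3 * L)), diameter = 2, length = L,
                     seed = 17)
    cfg <- planted_config(rod, bulk_box(30))
    lam <- gyration(unwrap_aggregate(cfg, seq_len(rod$a_s) - 1L,
                                     species = "B"))$lambda_sq
    tibble::tibble(L = L, l1 = lam[1], l2 = lam[2], l3 = lam[3])
  })
  expect_equal(rods$l3, lens^2 / 12, tolerance = 0.25)
  expect_lt(max(rods$l1), 1)           # short axes set by the diameter
  expect_gt(rods$l3[4] / rods$l1[4], 5)
  # sphere-rod discrimination via asphericity
  ball <- gyration(lattice_sphere(3, 0.4))
  expect_lt(asphericity(ball) / ball$rg_sq, 0.05)
  expect_gt(asphericity(c(rods$l1[4], rods$l2[4], rods$l3[4])), 5)
})

test_that("shape_vs_size averages per association number and feeds the exponent fit", {
  box <- bulk_box(18)
  objs <- list(plant_micelle(4, center = c(4, 4, 4), seed = 1),
               plant_micelle(4, center = c(13, 13, 13), seed = 2),
               plant_micelle(9, center = c(4, 13, 4), seed = 3))
  cfg <- planted_config(objs, box)
  sh <- shape_vs_size(list(cfg))
  expect_setequal(unique(sh$subset), c("core", "whole"))
  core <- sh[sh$subset == "core", ]
  expect_equal(core$n_obs[core$a_s == 4], 2)
  expect_equal(core$n_obs[core$a_s == 9], 1)
  # whole aggregates (core + corona) are larger than their cores
  whole <- sh[sh$subset == "whole", ]
  expect_true(all(whole$rg_sq > core$rg_sq))
  # single aggregate: the mean is that aggregate's own value
  one <- planted_config(objs[3], box)
  sh1 <- shape_vs_size(list(one))
  lam <- gyration(unwrap_aggregate(one, 0:8, species = "B"))$lambda_sq
  expect_equal(sh1$lambda3_sq[sh1$subset == "core"], lam[3], tolerance = 1e-10)
})
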
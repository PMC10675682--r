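test_that("conservative force is soft, repulsive and cut off at r_c", {
  expect_equal(conservative_force(c(1, 0, 0), 25), c(0, 0, 0))
  expect_equal(conservative_force(c(0.5, 0, 0), 25), c(12.5, 0, 0))
  expect_equal(conservative_force(c(1.7, 0, 0), 40), c(0, 0, 0))
  # finite everywhere, direction along the separation
  f <- conservative_force(c(0.3, 0.4, 0), 25)
  expect_equal(f, 25 * 0.5 * c(0.6, 0.8, 0))
  expect_equal(conservative_force(c(0, 0, 0), 25), c(0, 0, 0))
})

test_that("dissipative force damps only the radial relative velocity", {
  expect_equal(dissipative_force(c(0.5, 0, 0), c(0, 1, 0), gamma = 4.5),
               c(0, 0, 0))
  f <- dissipative_force(c(0.5, 0, 0), c(1, 0, 0), gamma = 4.5)
  expect_equal(sqrt(sum(f^2)), 4.5 * 0.25)  # gamma * w_R^2 * 1
  expect_equal(f[1], -1.125)                # opposes approach... separation
})

test_that("random force has zero mean and is antisymmetric via the shared variate", {
  withr::local_seed(99)
  n <- 1e5
  draws <- vapply(seq_len(n),
                  function(i) random_force(c(0.5, 0, 0), dt = 0.05)[1],
                  numeric(1))
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws)), 4 * se)
  # same theta, swapped roles: exact antisymmetry
  f_ij <- random_force(c(0.5, 0.2, 0), theta = 0.7)
  f_ji <- random_force(-c(0.5, 0.2, 0), theta = 0.7)
  expect_equal(f_ij, -f_ji)
})

test_that("bond force is harmonic about r0 and obeys Newton's third law", {
  expect_equal(bond_force(c(0.3, 0, 0), K = 4, r0 = 0.3), c(0, 0, 0))
  f <- bond_force(c(1, 0, 0), K = 4, r0 = 0)
  expect_equal(f, c(-4, 0, 0))  # magnitude K * r, attractive
  expect_equal(bond_force(c(0.2, -0.5, 0.1)), -bond_force(-c(0.2, -0.5, 0.1)))
})

test_that("wall force is linear within its range and vanishes beyond", {
  expect_equal(wall_force(1.2, 25, 1.2), 0)
  expect_equal(wall_force(0, 25, 1.2), 25)
  expect_equal(wall_force(0.6, 25, 1.2), 12.5)
  expect_equal(wall_force(2, 25, 1.2), 0)
})

test_that("hard reflection inverts the normal component and conserves energy", {
  r <- reflect_at_wall(c(-5.3, 1, 2), c(-2, 1, 0), D = 10)
  expect_equal(r$velocity, c(2, 1, 0))
  expect_equal(r$position[1], -4.7)
  tang <- reflect_at_wall(c(3, 0, 0), c(0, 1.5, -0.5), D = 10)
  expect_equal(tang$velocity, c(0, 1.5, -0.5))
  expect_equal(sum(r$velocity^2), sum(c(-2, 1, 0)^2))
})

test_that("compiled force evaluation matches the plain-R reference", {
  it <- interaction_table()
  for (seed in 1:3) {
    cfg <- build_bulk(4, box = bulk_box(5), seed = seed)
    f_ref <- slitmicelle:::dpd_forces_reference(cfg, it)
    bonds <- slitmicelle:::config_bonds(cfg)
    f_cpp <- slitmicelle:::cpp_compute_forces(
      cbind(cfg$x, cfg$y, cfg$z), cbind(cfg$vx, cfg$vy, cfg$vz),
      slitmicelle:::species_code(cfg$species), cfg$frozen, bonds$i, bonds$j,
      4, 0, unname(it$a), it$gamma,
      slitmicelle:::box_for_cpp(config_box(cfg)), TRUE, TRUE, TRUE)
    expect_equal(f_cpp, f_ref, tolerance = 1e-12)
  }
  # slit geometry with frozen walls and the soft wall potential
  cfg <- build_slit(3, box = slit_box(5, 5, 5), seed = 2)
  f_ref <- slitmicelle:::dpd_forces_reference(cfg, it)
  bonds <- slitmicelle:::config_bonds(cfg)
  f_cpp <- slitmicelle:::cpp_compute_forces(
    cbind(cfg$x, cfg$y, cfg$z), cbind(cfg$vx, cfg$vy, cfg$vz),
    slitmicelle:::species_code(cfg$species), cfg$frozen, bonds$i, bonds$j,
    4, 0, unname(it$a), it$gamma,
    slitmicelle:::box_for_cpp(config_box(cfg)), TRUE, TRUE, TRUE)
  expect_equal(f_cpp[!cfg$frozen, ], f_ref[!cfg$frozen, ], tolerance = 1e-12)
})

test_that("pair forces are exactly antisymmetric so bulk momentum is conserved", {
  cfg <- build_bulk(5, box = bulk_box(6), seed = 8)
  tr <- dpd_run(cfg, interaction_table(), steps = 2000, sample_period = 1000,
                log_period = 500, seed = 5)
  g <- glance(tr)
  expect_lt(g$max_momentum_per_bead, 1e-10)
})

test_that("thermostat holds kT near 1 on a short solvent run", {
  cfg <- build_bulk(0, box = bulk_box(6), seed = 2)
  tr <- dpd_run(cfg, interaction_table(), steps = 3000,
                pre_equil_steps = 500, sample_period = 500,
                log_period = 100, seed = 9)
  expect_gt(glance(tr)$kT_mean, 0.9)
  expect_lt(glance(tr)$kT_mean, 1.15)
})

test_that("with all forces off, beads fly freely and frozen beads never move", {
  box <- bulk_box(10)
  beads <- tibble::tibble(
    species = rep("S", 4),
    x = c(1, 2, 3, 4), y = c(1, 1, 1, 1), z = c(2, 2, 2, 2),
    vx = c(0.5, -0.25, 0, 1), vy = 0, vz = c(0, 0.1, 0, -0.3),
    chain_id = -1L, frozen = FALSE
  )
  cfg <- make_config(beads, box)
  free <- interaction_table(a = list(SS = 0), gamma = 0, sigma = 0)
  tr <- dpd_run(cfg, free, steps = 100, sample_period = 100, dt = 0.05,
                seed = 1)
  got <- tr$frames[[1]]
  expect_equal(got$x, (beads$x + beads$vx * 5) %% 10, tolerance = 1e-12)
  expect_equal(got$z, (beads$z + beads$vz * 5) %% 10, tolerance = 1e-12)
  expect_equal(got$vx, beads$vx)

  # zero velocities and zero forces: a fixed point
  beads0 <- dplyr::mutate(beads, vx = 0, vy = 0, vz = 0)
  tr0 <- dpd_run(make_config(beads0, box), free, steps = 50,
                 sample_period = 50, seed = 1)
  expect_equal(tr0$frames[[1]]$x, beads0$x)

  # frozen wall beads stay put under full interactions
  cfg_s <- build_slit(3, box = slit_box(5, 5, 5), seed = 3)
  tr_s <- dpd_run(cfg_s, interaction_table(), steps = 500,
                  sample_period = 500, seed = 3)
  expect_identical(tr_s$frames[[1]]$x[cfg_s$frozen], cfg_s$x[cfg_s$frozen])
})

test_that("slit runs keep every mobile bead between the reflecting planes", {
  cfg <- build_slit(4, box = slit_box(5, 6, 6), seed = 6)
  tr <- dpd_run(cfg, interaction_table(wall = "strong_attract"), steps = 1000,
                sample_period = 250, seed = 4)
  for (fr in tr$frames) {
    expect_true(all(abs(fr$x[!fr$frozen]) <= 2.5))
  }
})

test_that("trajectories are bit-identical for identical seeds", {
  cfg <- build_bulk(3, box = bulk_box(5), seed = 1)
  t1 <- dpd_run(cfg, interaction_table(), steps = 300, sample_period = 100,
                seed = 21)
  t2 <- dpd_run(cfg, interaction_table(), steps = 300, sample_period = 100,
                seed = 21)
  t3 <- dpd_run(cfg, interaction_table(), steps = 300, sample_period = 100,
                seed = 22)
  expect_identical(t1$frames[[3]]$x, t2$frames[[3]]$x)
  expect_identical(t1$frames[[3]]$vz, t2$frames[[3]]$vz)
  expect_false(identical(t1$frames[[3]]$x, t3$frames[[3]]$x))
})

test_that("instantaneous temperature follows equipartition", {
  box <- bulk_box(20)
  n <- 1e4
  withr::local_seed(31)
  beads <- tibble::tibble(
    species = "S", x = runif(n, 0, 20), y = runif(n, 0, 20),
    z = runif(n, 0, 20), vx = rnorm(n), vy = rnorm(n), vz = rnorm(n),
    chain_id = -1L, frozen = FALSE
  )
  cfg <- make_config(beads, box)
  expect_equal(measure_temperature(cfg), 1, tolerance = 0.02)
  hot <- dplyr::mutate(beads, vx = 2 * vx, vy = 2 * vy, vz = 2 * vz)
  expect_equal(measure_temperature(make_config(hot, box)),
               4 * measure_temperature(cfg))
  cold <- dplyr::mutate(beads, vx = 0, vy = 0, vz = 0)
  expect_equal(measure_temperature(make_config(cold, box)), 0)
})
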
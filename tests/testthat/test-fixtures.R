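test_that("planted micelles honor geometry, composition and determinism", {
  m <- plant_micelle(6, core_radius = 1.5, center = c(3, 4, 5), seed = 2)
  expect_s3_class(m, "planted_object")
  expect_equal(m$a_s, 6)
  b <- m$beads
  expect_equal(nrow(b), 60)
  expect_equal(sort(unique(b$chain_local)), 0:5)
  rB <- sqrt((b$x - 3)^2 + (b$y - 4)^2 + (b$z - 5)^2)[b$species == "B"]
  rA <- sqrt((b$x - 3)^2 + (b$y - 4)^2 + (b$z - 5)^2)[b$species == "A"]
  expect_true(all(rB <= 1.5 + 1e-12))
  expect_true(all(rA >= 1.5 - 1e-12 & rA <= 2.5 + 1e-12))
  expect_identical(plant_micelle(6, center = c(3, 4, 5), seed = 2)$beads, m$beads)
  # too-dilute cores cannot satisfy the contact criterion
  expect_error(plant_micelle(2, core_radius = 30, seed = 1), "dilute")
})

test_that("every planted object is one aggregate under the contact rule", {
  box <- bulk_box(40)
  for (seed in 1:5) {
    for (obj in list(plant_micelle(sample(1:12, 1), center = c(20, 20, 20),
                                   seed = seed),
                     plant_rod(15, diameter = 2, length = 6,
                               center = c(20, 20, 20), seed = seed))) {
      cfg <- planted_config(obj, box)
      aggs <- cluster_aggregates(cfg)
      expect_equal(nrow(aggs), 1)
      expect_equal(aggs$a_s, obj$a_s)
    }
  }
})

test_that("pancakes guarantee adsorption; thickness beyond the cutoff is refused", {
  box <- slit_box(8, 10, 10)
  pk <- plant_pancake(5, box, side = "upper", seed = 4)
  cfg <- planted_config(pk, box)
  xB <- cfg$x[cfg$species == "B"]
  expect_true(all(xB >= 4 - 1 & xB <= 4))
  expect_equal(unique(classify_adsorption(cfg)$label), "adsorbed")
  expect_error(plant_pancake(5, box, thickness = 1.4), "cutoff")
  expect_error(plant_pancake(5, bulk_box(8)), "slit")
})

test_that("planted_config offsets chains, wraps coordinates, and keeps truth", {
  box <- bulk_box(12)
  objs <- list(plant_micelle(3, center = c(6, 6, 6), seed = 1),
               plant_micelle(4, center = c(0.5, 11.5, 2), seed = 2))
  cfg <- planted_config(objs, box)
  expect_setequal(unique(cfg$chain_id), 0:6)
  expect_true(all(cfg$x >= 0 & cfg$x < 12))
  tr <- planted_truth(cfg)
  expect_equal(tr$a_s, c(3, 4))
  expect_equal(tr$chains[[2]], 3:6)
  expect_true(all(is.na(tr$label)))  # bulk: no adsorption labels
  expect_error(planted_truth(build_bulk(1, box = bulk_box(5))), "truth")
  # beads outside a slit are an assembly error, not silent clipping
  tall <- plant_micelle(3, center = c(0, 6, 6), seed = 1)
  expect_error(planted_config(tall, slit_box(4, 12, 12)), "outside")
})

test_that("scene truth matches the recovered partition and labels", {
  cfg <- plant_scene(slit_box(10, 14, 14), n_objects = 3, n_pancakes = 2,
                     seed = 31)
  tr <- planted_truth(cfg)
  labs <- classify_adsorption(cfg)
  expect_equal(nrow(labs), nrow(tr))
  expect_setequal(sort(labs$a_s), sort(tr$a_s))
  expect_equal(sum(labs$label == "adsorbed"), sum(tr$label == "adsorbed"))
  got <- lapply(labs$chains, sort)
  want <- lapply(tr$chains, sort)
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(want, paste, collapse = ","))
  expect_error(plant_scene(bulk_box(6), n_objects = 50, seed = 1), "small")
})

test_that("scenarios encode the study conditions at desk scale", {
  sc <- scenario("bulk-small")
  expect_equal(sc$box$Lx, 12)
  expect_equal(sc$n_chains, 133)  # 25.6% of 3 * 12^3 beads, 10 per chain
  expect_equal(sc$c_percent, 100 * 1330 / (3 * 1728), tolerance = 1e-12)
  expect_equal(sc$interactions$a["A", "B"], 40)
  expect_equal(sc$interactions$a["B", "W"], 25)

  sl <- scenario("slit-strong-attract")
  expect_equal(sl$box$D, 10)
  expect_equal(sl$n_chains, 111)  # 25.6% of 3 * 10 * 12^2 beads
  expect_equal(sl$interactions$a["B", "W"], 15)
  expect_equal(scenario("slit-repulsive")$interactions$a["B", "W"], 30)
  expect_equal(scenario("slit-weak-attract")$interactions$a["B", "W"], 20)
  expect_equal(sl$pre_equil_steps + sl$steps, 2e5)
  expect_error(scenario("slab"), "arg")
})

test_that("run_scenario wires the builder, interactions and integrator together", {
  tr <- run_scenario("bulk-small", seed = 3, steps = 200,
                     pre_equil_steps = 100, sample_period = 100,
                     log_period = 100)
  expect_s3_class(tr, "dpd_trajectory")
  expect_equal(length(tr$frames), 2)
  expect_equal(nrow(tr$frames[[1]]), round(3 * 12^3))
  g <- glance(tr)
  expect_lt(g$max_momentum_per_bead, 1e-10)
  expect_gt(g$kT_mean, 0.8)
  expect_lt(g$kT_mean, 1.3)
})
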
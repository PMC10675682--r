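test_that("contact counting matches the combinatorial limit and is symmetric", {
  box <- bulk_box(10)
  # two chains whose five B beads each sit at one point: 5 x 5 = 25 contacts
  pt <- function(id) tibble::tibble(
    species = chain_spec()$species,
    x = c(2 + 0.3 * (0:4), rep(2, 5)), y = 2, z = 2,
    chain_id = as.integer(id), frozen = FALSE, vx = 0, vy = 0, vz = 0)
  cfg <- make_config(dplyr::bind_rows(pt(0), pt(1)), box)
  ct <- contact_pairs(cfg)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$n_contacts, 25)
  expect_true(ct$chain_i < ct$chain_j)

  # identical extended chains with B beads 0.4 apart: pairs within the
  # cutoff are those with |i - j| <= 2, i.e. 5 + 8 + 6 = 19
  c1 <- straight_chain(c(2, 2, 2), 0)
  c2 <- straight_chain(c(2, 2, 2), 1)
  ct2 <- contact_pairs(make_config(dplyr::bind_rows(c1, c2), box))
  expect_equal(ct2$n_contacts, 19)

  # far apart: no contacts
  c3 <- straight_chain(c(7, 7, 7), 1)
  cfg2 <- make_config(dplyr::bind_rows(c1, c3), box)
  expect_equal(nrow(contact_pairs(cfg2)), 0)
})

test_that("contacts use minimum-image distances in periodic directions only", {
  box <- bulk_box(10)
  # B beads straddling the periodic boundary in z
  mk <- function(z0, id) tibble::tibble(
    species = "B", x = 1, y = 1, z = z0 + 0.05 * (0:4),
    chain_id = as.integer(id), frozen = FALSE, vx = 0, vy = 0, vz = 0)
  cfg <- make_config(dplyr::bind_rows(mk(9.8, 0), mk(0.1, 1)), box)
  expect_gt(contact_pairs(cfg)$n_contacts, 0)
  # same coordinates in a slit x direction: no wrap across the walls
  sbox <- slit_box(10, 10, 10)
  mkx <- function(x0, id) tibble::tibble(
    species = "B", x = x0 + 0.05 * (0:4), y = 1, z = 1,
    chain_id = as.integer(id), frozen = FALSE, vx = 0, vy = 0, vz = 0)
  cfgx <- make_config(dplyr::bind_rows(mkx(4.5, 0), mkx(-4.9, 1)), sbox)
  expect_equal(nrow(contact_pairs(cfgx)), 0)
})

test_that("clustering is transitive and the threshold acts as specified", {
  contacts <- tibble::tibble(chain_i = c(0L, 1L), chain_j = c(1L, 2L),
                             n_contacts = c(3L, 3L))
  aggs <- cluster_aggregates(contacts, threshold = 3, chains = 0:2)
  expect_equal(nrow(aggs), 1)
  expect_equal(aggs$a_s, 3)
  expect_setequal(aggs$chains[[1]], 0:2)

  # two contacts at threshold 3: unimers
  weak <- tibble::tibble(chain_i = 0L, chain_j = 1L, n_contacts = 2L)
  expect_equal(cluster_aggregates(weak, threshold = 3, chains = 0:1)$a_s,
               c(1, 1))
  # the same pair bonds at threshold 2
  expect_equal(cluster_aggregates(weak, threshold = 2, chains = 0:1)$a_s, 2)
  expect_error(cluster_aggregates(weak, threshold = 0, chains = 0:1),
               "at least 1")
  empty <- cluster_aggregates(weak[0, ], chains = integer())
  expect_equal(nrow(empty), 0)
})

test_that("clustering equals the brute-force transitive closure on random fixtures", {
  for (seed in 1:10) {
    box <- bulk_box(12)
    cfg <- plant_scene(box, n_objects = sample(2:4, 1), n_pancakes = 0,
                       a_s_range = c(1, 8), seed = seed)
    contacts <- contact_pairs(cfg)
    chains <- sort(unique(cfg$chain_id[cfg$chain_id >= 0]))
    got <- cluster_aggregates(cfg)
    want <- oracle_cluster(contacts, chains)
    got_sets <- lapply(got$chains, sort)
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
    # partition invariant: association numbers sum to the chain count
    expect_equal(sum(got$a_s), length(chains))
  }
})

test_that("lowering the contact threshold never increases the aggregate count", {
  for (seed in 1:5) {
    cfg <- plant_scene(bulk_box(12), n_objects = 3, n_pancakes = 0,
                       a_s_range = c(2, 10), seed = 100 + seed)
    counts <- vapply(4:1, function(th) nrow(cluster_aggregates(cfg, th)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("adsorption labelling follows the three-B-bead wall-contact rule", {
  box <- slit_box(10, 12, 12)
  half <- 5
  # chain pressed to the lower wall: 3 B beads within 1 r_c of the plane
  near <- tibble::tibble(
    species = chain_spec()$species,
    x = c(rep(-3, 5), -4.2, -4.2, -4.2, -3.8, -3.8),
    y = 6, z = 6 + 0.3 * (0:9), chain_id = 0L, frozen = FALSE,
    vx = 0, vy = 0, vz = 0)
  cfg <- make_config(near, box)
  labs <- classify_adsorption(cfg)
  expect_equal(labs$label, "adsorbed")

  # only 2 B beads in contact: free
  near2 <- dplyr::mutate(near, x = replace(x, 8, -3))
  expect_equal(classify_adsorption(make_config(near2, box))$label, "free")

  # whole-aggregate contagion: a clear chain bound to a touching chain
  pancake <- plant_pancake(4, box, side = "lower", seed = 2)
  cfg3 <- planted_config(list(pancake), box)
  labs3 <- classify_adsorption(cfg3)
  expect_equal(unique(labs3$label), "adsorbed")

  # bulk geometry is rejected
  expect_error(classify_adsorption(plant_scene(bulk_box(12), seed = 1)),
               "slit")
})

test_that("adsorbed and free labels partition the aggregates", {
  cfg <- plant_scene(slit_box(10, 14, 14), n_objects = 2, n_pancakes = 2,
                     seed = 7)
  labs <- classify_adsorption(cfg)
  expect_equal(sum(labs$label == "adsorbed") + sum(labs$label == "free"),
               nrow(labs))
})
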
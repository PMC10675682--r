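# Planted synthetic configurations with known ground truth, and
# scaled-down end-to-end simulation scenarios.
#
# The planted generators build idealized micelles, rods and wall
# pancakes directly (no simulation), verify post hoc that each object
# satisfies the three-contact aggregate criterion as a single connected
# component (rejection sampling with a deterministic retry schedule),
# and serialize the intended partition/labels so every analysis stage
# can be scored exactly.

uniform_in_sphere <- function(n, radius) {
  r <- radius * stats::runif(n)^(1 / 3)
  costh <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  sinth <- sqrt(1 - costh^2)
  cbind(r * sinth * cos(phi), r * sinth * sin(phi), r * costh)
}

uniform_in_shell <- function(n, r_in, r_out) {
  r <- (stats::runif(n, r_in^3, r_out^3))^(1 / 3)
  costh <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  sinth <- sqrt(1 - costh^2)
  cbind(r * sinth * cos(phi), r * sinth * sin(phi), r * costh)
}

# connectivity check in open space: one aggregate under the three-contact
# rule over the local (uncentered) coordinates
planted_is_connected <- function(beads, a_s, threshold = 3) {
  sel <- beads$species == "B"
  big <- max(abs(c(beads$x, beads$y, beads$z))) * 10 + 100
  m <- cpp_contact_pairs(cbind(beads$x[sel], beads$y[sel], beads$z[sel]),
                         chain = beads$chain_local[sel],
                         boxlen = rep(big, 3),
                         periodic = rep(FALSE, 3), rc = 1)
  contacts <- tibble::tibble(chain_i = m[, 1], chain_j = m[, 2],
                             n_contacts = m[, 3])
  aggs <- cluster_aggregates(contacts, threshold = threshold,
                             chains = 0:(a_s - 1))
  nrow(aggs) == 1 && aggs$a_s[1] == a_s
}

plant_with_retries <- function(a_s, seed, label, make_one, max_tries = 400) {
  for (try in seq_len(max_tries)) {
    beads <- withr::with_seed(seed + (try - 1) * 1000L, make_one())
    if (planted_is_connected(beads, a_s)) {
      return(structure(list(beads = beads, a_s = a_s, shape = label,
                            seed = seed, tries = try),
                       class = "planted_object"))
    }
  }
  rlang::abort(paste0(
    "could not realize the contact criterion for the requested geometry; ",
    "the core is too dilute (reduce the core size or raise A_S)"))
}

chain_beads_template <- function(a_s, chain) {
  tibble::tibble(
    species = rep(chain$species, a_s),
    chain_local = rep(0:(a_s - 1), each = chain$n)
  )
}

#' Plant an idealized spherical core-shell micelle
#'
#' `a_s` chains whose insoluble B beads are uniform in a sphere of
#' `core_radius` about `center` and whose soluble A beads occupy the
#' surrounding unit shell.  The construction is re-drawn (with a
#' deterministic retry schedule) until the whole object is a single
#' aggregate under the three-contact criterion, so [cluster_aggregates()]
#' recovers it exactly; an error is raised when the core is too dilute
#' for that guarantee.
#'
#' @param a_s Association number (>= 1).
#' @param core_radius Core radius (default 1.5 r_c).
#' @param center Length-3 center position.
#' @param chain A `dpd_chain` (default A5B5).
#' @param seed Seed; generation is seed-deterministic.
#' @return A `planted_object` (beads plus intended truth), to be
#'   assembled with [planted_config()].
#' @export
plant_micelle <- function(a_s, core_radius = 1.5, center = c(0, 0, 0),
                          chain = chain_spec(), seed = 1) {
  stopifnot(a_s >= 1, core_radius > 0)
  plant_with_retries(a_s, seed, "sphere", function() {
    tpl <- chain_beads_template(a_s, chain)
    nB <- sum(tpl$species == "B")
    nA <- sum(tpl$species == "A")
    pos <- matrix(NA_real_, nrow(tpl), 3)
    pos[tpl$species == "B", ] <- uniform_in_sphere(nB, core_radius)
    pos[tpl$species == "A", ] <- uniform_in_shell(nA, core_radius,
                                                  core_radius + 1)
    tpl$x <- pos[, 1] + center[1]
    tpl$y <- pos[, 2] + center[2]
    tpl$z <- pos[, 3] + center[3]
    tpl
  })
}

#' Plant an idealized rod-like (cylindrical) associate
#'
#' B beads uniform in a cylinder of the given `diameter` and `length`
#' (axis along `axis`, centered at `center`); A beads in the unit
#' annular shell around the core.  Same contact guarantee as
#' [plant_micelle()].  In the `length == diameter` limit the object's
#' shape metrics approach those of a planted sphere; long rods have one
#' dominant gyration eigenvalue growing as length^2 / 12.
#'
#' @param a_s Association number.
#' @param diameter Core diameter.
#' @param length Core length (>= diameter).
#' @param center Length-3 center.
#' @param axis Cylinder axis (normalized internally).
#' @param chain A `dpd_chain`.
#' @param seed Seed.
#' @return A `planted_object`.
#' @export
plant_rod <- function(a_s, diameter = 2, length, center = c(0, 0, 0),
                      axis = c(0, 0, 1), chain = chain_spec(), seed = 1) {
  stopifnot(a_s >= 1, diameter > 0, length >= diameter)
  u <- axis / sqrt(sum(axis^2))
  # orthonormal frame around u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  in_cyl <- function(n, r_in, r_out) {
    r <- sqrt(stats::runif(n, r_in^2, r_out^2))
    phi <- stats::runif(n, 0, 2 * pi)
    t <- stats::runif(n, -length / 2, length / 2)
    outer(t, u) + outer(r * cos(phi), e1) + outer(r * sin(phi), e2)
  }
  plant_with_retries(a_s, seed, "rod", function() {
    tpl <- chain_beads_template(a_s, chain)
    nB <- sum(tpl$species == "B")
    nA <- sum(tpl$species == "A")
    pos <- matrix(NA_real_, nrow(tpl), 3)
    pos[tpl$species == "B", ] <- in_cyl(nB, 0, diameter / 2)
    pos[tpl$species == "A", ] <- in_cyl(nA, diameter / 2, diameter / 2 + 1)
    tpl$x <- pos[, 1] + center[1]
    tpl$y <- pos[, 2] + center[2]
    tpl$z <- pos[, 3] + center[3]
    tpl
  })
}

#' Plant a pancake-like adsorbed associate at a slit wall
#'
#' B beads uniform in a flat disk pressed against the chosen reflecting
#' plane (within `thickness` of it), A beads in a slab just above; every
#' chain therefore has all of its B beads inside the wall-contact
#' cutoff, so [classify_adsorption()] is guaranteed to label the object
#' adsorbed.  Requesting a `thickness` above the wall-contact cutoff
#' voids that guarantee and is an error.
#'
#' @param a_s Association number.
#' @param box A slit `dpd_box`.
#' @param side `"lower"` (`x = -D/2`) or `"upper"`.
#' @param radius Disk radius (default 2.5).
#' @param thickness Disk thickness (default 0.8; must not exceed
#'   `wall_cutoff`).
#' @param center_yz Lateral center (default box center).
#' @param chain A `dpd_chain`.
#' @param wall_cutoff Wall-contact distance the guarantee refers to
#'   (default 1).
#' @param seed Seed.
#' @return A `planted_object` with shape `"pancake"`.
#' @export
plant_pancake <- function(a_s, box, side = c("lower", "upper"), radius = 2.5,
                          thickness = 0.8, center_yz = NULL,
                          chain = chain_spec(), wall_cutoff = 1, seed = 1) {
  side <- match.arg(side)
  stopifnot(box$kind == "slit", a_s >= 1, radius > 0)
  if (thickness > wall_cutoff) {
    rlang::abort("thickness exceeds the wall-contact cutoff; adsorption cannot be guaranteed")
  }
  if (is.null(center_yz)) center_yz <- c(box$Ly / 2, box$Lz / 2)
  half <- box$D / 2
  x_wall <- if (side == "lower") -half else half
  sgn <- if (side == "lower") 1 else -1
  disk <- function(n, x_lo, x_hi) {
    r <- radius * sqrt(stats::runif(n))
    phi <- stats::runif(n, 0, 2 * pi)
    cbind(x_wall + sgn * stats::runif(n, x_lo, x_hi),
          center_yz[1] + r * cos(phi),
          center_yz[2] + r * sin(phi))
  }
  obj <- plant_with_retries(a_s, seed, "pancake", function() {
    tpl <- chain_beads_template(a_s, chain)
    nB <- sum(tpl$species == "B")
    nA <- sum(tpl$species == "A")
    pos <- matrix(NA_real_, nrow(tpl), 3)
    pos[tpl$species == "B", ] <- disk(nB, 1e-3, thickness)
    pos[tpl$species == "A", ] <- disk(nA, thickness, thickness + 1)
    tpl$x <- pos[, 1]; tpl$y <- pos[, 2]; tpl$z <- pos[, 3]
    tpl
  })
  obj$side <- side
  obj
}

#' Assemble planted objects into a configuration with ground truth
#'
#' Offsets chain ids so each object keeps its identity, wraps lateral
#' coordinates into the box, and attaches the intended partition and
#' adsorption labels as the `truth` attribute (see [planted_truth()]).
#' Placement is the caller's responsibility: objects whose beads come
#' within the contact cutoff of each other may merge and then no longer
#' match their truth.  Velocities are zero (these are analysis fixtures,
#' not dynamical states).
#'
#' @param objects List of `planted_object`s (or a single one).
#' @param box A `dpd_box`.
#' @param chain A `dpd_chain` (default A5B5).
#' @return A `dpd_config` with attribute `truth`.
#' @export
planted_config <- function(objects, box, chain = chain_spec()) {
  if (inherits(objects, "planted_object")) objects <- list(objects)
  offset <- 0L
  half <- if (box$kind == "slit") box$D / 2 else NULL
  beads <- purrr::imap_dfr(objects, function(obj, i) {
    b <- obj$beads
    b$chain_id <- b$chain_local + offset
    offset <<- offset + obj$a_s
    b$object <- i
    b
  })
  # wrap periodic coordinates into the primary box
  if (box$kind == "bulk") beads$x <- beads$x %% box$Lx
  beads$y <- beads$y %% box$Ly
  beads$z <- beads$z %% box$Lz
  if (box$kind == "slit" && any(abs(beads$x) > half)) {
    rlang::abort("planted beads fall outside the slit")
  }
  cfg <- dpd_config(
    tibble::tibble(species = beads$species, x = beads$x, y = beads$y,
                   z = beads$z, vx = 0, vy = 0, vz = 0,
                   chain_id = beads$chain_id, frozen = FALSE),
    box = box, chain = chain
  )
  offsets <- cumsum(c(0L, purrr::map_int(objects, "a_s")))
  truth <- purrr::imap_dfr(objects, function(obj, i) {
    tibble::tibble(
      object = i, shape = obj$shape, a_s = obj$a_s,
      chains = list(offsets[i] + 0:(obj$a_s - 1)),
      label = if (obj$shape == "pancake") "adsorbed"
              else if (box$kind == "slit") "free" else NA_character_
    )
  })
  attr(cfg, "truth") <- truth
  cfg
}

#' Ground truth of a planted configuration
#'
#' @param config A `dpd_config` built by [planted_config()] (or read
#'   back with its truth sidecar).
#' @return Tibble with `object`, `shape`, `a_s`, `chains` (list-column)
#'   and intended `label`.
#' @export
planted_truth <- function(config) {
  tr <- attr(config, "truth")
  if (is.null(tr)) rlang::abort("configuration carries no planted truth")
  tr
}

#' Randomly composed planted scene
#'
#' Draws a mix of micelles (and, in slits, wall pancakes) with random
#' association numbers, placed on a jittered grid with enough clearance
#' that distinct objects can never share a contact, so the planted truth
#' is recoverable exactly.  Used for end-to-end validation of the
#' clustering and adsorption pipeline.
#'
#' @param box A `dpd_box`.
#' @param n_objects Number of free objects (default 3).
#' @param n_pancakes Number of adsorbed pancakes (slit boxes only,
#'   default 1).
#' @param a_s_range Inclusive range association numbers are drawn from.
#' @param seed Seed.
#' @return A `dpd_config` with attribute `truth`.
#' @export
plant_scene <- function(box, n_objects = 3, n_pancakes = if (box$kind == "slit") 1 else 0,
                        a_s_range = c(1, 12), seed = 1) {
  stopifnot(n_objects >= 0, n_pancakes >= 0, n_objects + n_pancakes >= 1)
  if (n_pancakes > 0 && box$kind != "slit") {
    rlang::abort("pancakes require a slit box")
  }
  withr::local_seed(seed)
  core_r <- 1.3
  extent <- core_r + 1          # core + corona
  spacing <- 2 * extent + 1.2   # clearance > contact cutoff
  Ls <- c(if (box$kind == "bulk") box$Lx else box$D - 2.4, box$Ly, box$Lz)
  slots <- pmax(1, floor(Ls / spacing))
  if (prod(slots) < n_objects) {
    rlang::abort("box too small for that many well-separated objects")
  }
  grid <- expand.grid(i = seq_len(slots[1]), j = seq_len(slots[2]),
                      k = seq_len(slots[3]))
  pick <- grid[sample(nrow(grid), n_objects), , drop = FALSE]
  a_s <- sample(a_s_range[1]:a_s_range[2], n_objects + n_pancakes,
                replace = TRUE)
  seeds <- sample.int(1e6, n_objects + n_pancakes)
  objects <- purrr::map(seq_len(n_objects), function(m) {
    ctr <- (as.numeric(pick[m, ]) - 0.5) * spacing
    if (box$kind == "slit") ctr[1] <- ctr[1] - (box$D - 2.4) / 2
    plant_micelle(a_s[m], core_radius = core_r, center = ctr,
                  seed = seeds[m])
  })
  if (n_pancakes > 0) {
    # lateral grid at the lower wall, same clearance logic
    pk_r <- 1.6
    pk_spacing <- 2 * (pk_r + 1) + 1.2
    nyz <- pmax(1, floor(c(box$Ly, box$Lz) / pk_spacing))
    if (prod(nyz) < n_pancakes) {
      rlang::abort("wall too small for that many well-separated pancakes")
    }
    gyz <- expand.grid(j = seq_len(nyz[1]), k = seq_len(nyz[2]))
    pickw <- gyz[sample(nrow(gyz), n_pancakes), , drop = FALSE]
    pks <- purrr::map(seq_len(n_pancakes), function(m) {
      plant_pancake(a_s[n_objects + m], box, side = "lower", radius = pk_r,
                    center_yz = (as.numeric(pickw[m, ]) - 0.5) * pk_spacing,
                    seed = seeds[n_objects + m])
    })
    objects <- c(objects, pks)
  }
  planted_config(objects, box)
}

#' Scaled-down end-to-end simulation scenarios
#'
#' Named parameter sets for short self-contained runs that exhibit the
#' physics of the full-scale study at desk scale: a 12^3 bulk box or a
#' D = 10 x 12^2 slit at bead density 3 and copolymer concentration
#' 25.6 percent, with the four wall-affinity presets (`a_BW` = 30 / 25 /
#' 20 / 15 for repulsive / inert / weakly / strongly attractive walls)
#' and a 2 x 10^5-step schedule (a quarter of it pre-equilibration).
#'
#' @param name One of `"bulk-small"`, `"slit-inert"`, `"slit-repulsive"`,
#'   `"slit-weak-attract"`, `"slit-strong-attract"`.
#' @return List with `name`, `box`, `interactions`, `chain`, `rho`,
#'   `n_chains`, `c_percent`, `pre_equil_steps`, `steps`,
#'   `sample_period`.
#' @export
scenario <- function(name = c("bulk-small", "slit-inert", "slit-repulsive",
                              "slit-weak-attract", "slit-strong-attract")) {
  name <- match.arg(name)
  box <- if (name == "bulk-small") bulk_box(12) else slit_box(10, 12, 12)
  wall <- switch(name,
    "bulk-small" = "inert",
    "slit-inert" = "inert",
    "slit-repulsive" = "repulsive",
    "slit-weak-attract" = "weak_attract",
    "slit-strong-attract" = "strong_attract"
  )
  c_target <- 25.6
  n_chains <- chains_for_concentration(c_target, volume = box_volume(box),
                                       quiet = TRUE)
  list(name = name, box = box, interactions = interaction_table(wall = wall),
       chain = chain_spec(), rho = 3, n_chains = n_chains,
       c_percent = concentration(n_chains, volume = box_volume(box)),
       pre_equil_steps = 5e4, steps = 1.5e5, sample_period = 1e3)
}

#' Build and run a scenario
#'
#' Convenience wrapper: builds the initial configuration for a
#' [scenario()] and integrates it.
#'
#' @param scn A scenario list from [scenario()] (or its name).
#' @param seed Seed used for both the build and the thermostat noise.
#' @param ... Overrides passed to [dpd_run()] (e.g. shorter `steps`).
#' @return A `dpd_trajectory`.
#' @export
run_scenario <- function(scn, seed = 1, ...) {
  if (is.character(scn)) scn <- scenario(scn)
  cfg <- if (scn$box$kind == "bulk") {
    build_bulk(scn$n_chains, scn$chain, scn$box, scn$rho, seed = seed)
  } else {
    build_slit(scn$n_chains, scn$chain, scn$box, scn$rho, seed = seed)
  }
  args <- list(config = cfg, interactions = scn$interactions,
               steps = scn$steps, pre_equil_steps = scn$pre_equil_steps,
               sample_period = scn$sample_period, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(dpd_run, args)
}
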
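# Time integration and the individual force laws.
#
# The production path is the compiled engine (cell lists, Groot-Warren
# modified velocity-Verlet).  The force laws are additionally exposed as
# small plain-R functions, both as executable documentation of the model
# and as an independent reference the test suite compares the compiled
# engine against.

species_code <- function(species) {
  match(species, DPD_SPECIES) - 1L
}

box_for_cpp <- function(box) {
  list(kind = if (box$kind == "bulk") 0L else 1L,
       Lx = if (box$kind == "bulk") box$Lx else box$D,
       Ly = box$Ly, Lz = box$Lz,
       x_c = box$x_c %||% 0, a_wall = box$a_wall %||% 0)
}

# consecutive-bead bond list (0-based indices) from the chain_id column;
# beads of a chain are stored contiguously in block order
config_bonds <- function(config) {
  idx <- which(config$chain_id >= 0L)
  if (!length(idx)) return(list(i = integer(), j = integer()))
  same <- config$chain_id[idx[-length(idx)]] == config$chain_id[idx[-1]]
  list(i = idx[-length(idx)][same] - 1L, j = idx[-1][same] - 1L)
}

#' Soft conservative DPD pair force
#'
#' `F^C = a_ij (1 - r / r_c) e_ij` for `r < r_c` and zero beyond; the
#' force on bead i points away from bead j (pure repulsion) and stays
#' finite at any separation, which is what lets DPD beads interpenetrate.
#' At exact coincidence the direction is undefined and the force is taken
#' as zero.
#'
#' @param r_ij Separation vector from bead j to bead i (length 3).
#' @param a_ij Maximum repulsion (kT / r_c).
#' @param r_c Cutoff (default 1).
#' @return Force vector acting on bead i.
#' @export
conservative_force <- function(r_ij, a_ij, r_c = 1) {
  r <- sqrt(sum(r_ij^2))
  if (r >= r_c || r < 1e-12) return(c(0, 0, 0))
  a_ij * (1 - r / r_c) * r_ij / r
}

#' Dissipative (friction) DPD pair force
#'
#' `F^D = -gamma w_D(r) (e_ij . v_ij) e_ij` with `w_D = (1 - r/r_c)^2`;
#' it damps the radial component of the relative velocity only, so a
#' purely tangential relative motion feels no friction.
#'
#' @param r_ij Separation vector (j to i).
#' @param v_ij Relative velocity `v_i - v_j`.
#' @param gamma Friction coefficient.
#' @param r_c Cutoff.
#' @return Force vector on bead i.
#' @export
dissipative_force <- function(r_ij, v_ij, gamma = 4.5, r_c = 1) {
  r <- sqrt(sum(r_ij^2))
  if (r >= r_c || r < 1e-12) return(c(0, 0, 0))
  e <- r_ij / r
  w <- (1 - r / r_c)
  -gamma * w^2 * sum(e * v_ij) * e
}

#' Random (thermal) DPD pair force
#'
#' `F^R = sigma w_R(r) theta dt^(-1/2) e_ij`, with `theta` a zero-mean,
#' unit-variance variate drawn once per interacting pair per step and
#' shared by both partners, so `F^R_ij = -F^R_ji` and momentum is
#' conserved.  Together with the dissipative force and the balance
#' `sigma^2 = 2 gamma kT` this thermostats the system.
#'
#' @param r_ij Separation vector (j to i).
#' @param sigma Noise amplitude.
#' @param dt Timestep (enters as `1/sqrt(dt)`).
#' @param theta The shared pair variate; default draws uniform on
#'   `[-sqrt(3), sqrt(3)]` (unit variance).
#' @param r_c Cutoff.
#' @return Force vector on bead i.
#' @export
random_force <- function(r_ij, sigma = 3, dt = 0.05,
                         theta = stats::runif(1, -sqrt(3), sqrt(3)),
                         r_c = 1) {
  r <- sqrt(sum(r_ij^2))
  if (r >= r_c || r < 1e-12) return(c(0, 0, 0))
  sigma * (1 - r / r_c) * theta / sqrt(dt) * r_ij / r
}

#' Harmonic bond force
#'
#' From `U = (K/2) (r - r0)^2`: magnitude `K |r - r0|`, pulling the
#' bonded beads toward separation `r0`.
#'
#' @param r_ij Separation vector (j to i).
#' @param K Spring constant.
#' @param r0 Equilibrium bond length.
#' @return Force vector on bead i.
#' @export
bond_force <- function(r_ij, K = 4, r0 = 0) {
  r <- sqrt(sum(r_ij^2))
  if (r < 1e-12) return(c(0, 0, 0))
  -K * (r - r0) * r_ij / r
}

#' Soft repulsive wall force
#'
#' From the wall potential `U(x) = (a_wall x_c / 2) (1 - x / x_c)^2` for
#' `x < x_c` (zero beyond): magnitude `a_wall (1 - x / x_c)` directed
#' into the slit, where `x` is the distance to the nearest reflecting
#' plane.  Applied to every mobile species with the same amplitude;
#' species-selective wall affinity is carried by the frozen wall beads.
#'
#' @param x_dist Distance to the nearest plane (>= 0).
#' @param a_wall Amplitude (default 25).
#' @param x_c Range (default 1.2).
#' @return Scalar force magnitude (>= 0), directed into the slit.
#' @export
wall_force <- function(x_dist, a_wall = 25, x_c = 1.2) {
  stopifnot(all(x_dist >= 0))
  ifelse(x_dist < x_c, a_wall * (1 - x_dist / x_c), 0)
}

#' Hard reflection at a slit wall
#'
#' A bead crossing `x = +-D/2` is mirrored back about the plane; the
#' velocity component normal to the wall is inverted and the tangential
#' components are unchanged, so kinetic energy is conserved.
#'
#' @param position Length-3 position with possibly `|x| > D/2`.
#' @param velocity Length-3 velocity.
#' @param D Slit width.
#' @return List with reflected `position` and `velocity`.
#' @export
reflect_at_wall <- function(position, velocity, D) {
  half <- D / 2
  x <- position[1]; vx <- velocity[1]
  while (abs(x) > half) {
    x <- if (x > half) 2 * half - x else -2 * half - x
    vx <- -vx
  }
  list(position = c(x, position[2], position[3]),
       velocity = c(vx, velocity[2], velocity[3]))
}

#' Instantaneous kinetic temperature
#'
#' `kT_inst = sum(m |v|^2) / (3 N_mobile - 3)`, with three degrees of
#' freedom removed for the conserved total momentum.
#'
#' @param config A `dpd_config`.
#' @return Scalar temperature in kT units.
#' @export
measure_temperature <- function(config) {
  mob <- !config$frozen
  n <- sum(mob)
  if (n < 2) return(0)
  sum(config$vx[mob]^2 + config$vy[mob]^2 + config$vz[mob]^2) / (3 * n - 3)
}

# plain-R total force (conservative + dissipative + bonds + wall), O(N^2);
# reference oracle for the compiled engine on tiny systems
dpd_forces_reference <- function(config, interactions,
                                 with_dissipative = TRUE) {
  box <- config_box(config)
  n <- nrow(config)
  pos <- cbind(config$x, config$y, config$z)
  vel <- cbind(config$vx, config$vy, config$vz)
  per <- box$periodic
  L <- c(if (box$kind == "bulk") box$Lx else box$D, box$Ly, box$Lz)
  f <- matrix(0, n, 3)
  gamma <- if (with_dissipative) interactions$gamma else 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (config$frozen[i] && config$frozen[j]) next
      d <- pos[i, ] - pos[j, ]
      for (k in 1:3) if (per[k]) d[k] <- d[k] - L[k] * round(d[k] / L[k])
      a_ij <- interactions$a[config$species[i], config$species[j]]
      fc <- conservative_force(d, a_ij) +
        dissipative_force(d, vel[i, ] - vel[j, ], gamma)
      f[i, ] <- f[i, ] + fc
      f[j, ] <- f[j, ] - fc
    }
  }
  bonds <- config_bonds(config)
  chain <- config_chain(config) %||% chain_spec()
  for (b in seq_along(bonds$i)) {
    i <- bonds$i[b] + 1L; j <- bonds$j[b] + 1L
    d <- pos[i, ] - pos[j, ]
    for (k in 1:3) if (per[k]) d[k] <- d[k] - L[k] * round(d[k] / L[k])
    fb <- bond_force(d, chain$K, chain$r0)
    f[i, ] <- f[i, ] + fb
    f[j, ] <- f[j, ] - fb
  }
  if (box$kind == "slit") {
    half <- box$D / 2
    for (i in which(!config$frozen)) {
      d <- half - abs(pos[i, 1])
      if (d >= 0 && d < box$x_c) {
        f[i, 1] <- f[i, 1] - sign(pos[i, 1]) * wall_force(d, box$a_wall, box$x_c)
      }
    }
  }
  f
}

#' Run a DPD simulation
#'
#' Integrates the configuration with the Groot-Warren modified
#' velocity-Verlet scheme (velocity prediction factor `lambda`, default
#' 0.65, the standard companion to `gamma = 4.5`, `sigma = 3`,
#' `dt = 0.05`).  Frozen wall beads never move; mobile beads are wrapped
#' in periodic directions and hard-reflected at slit walls.  The run
#' refuses interaction tables that violate the fluctuation-dissipation
#' balance `sigma^2 = 2 gamma kT`.
#'
#' Identical inputs and seed give a bit-identical trajectory.
#'
#' @param config Starting `dpd_config`.
#' @param interactions A `dpd_interactions` table.
#' @param steps Production steps.
#' @param pre_equil_steps Pre-equilibration steps run before sampling.
#' @param sample_period Store a frame every this many production steps.
#' @param dt Timestep in tau (default 0.05).
#' @param lambda Velocity-prediction factor of the integrator.
#' @param seed Integer seed for the thermostat noise.
#' @param log_period Record instantaneous kT and total momentum every
#'   this many steps (default `sample_period`).
#' @return A `dpd_trajectory`: list with `frames` (list of
#'   `dpd_config`), `log` (tibble: step, kT, px, py, pz), `overlaps`
#'   (count of exactly coincident pairs encountered) and `params`.
#' @examples
#' \donttest{
#' cfg <- build_bulk(0, box = bulk_box(5), seed = 1)
#' tr <- dpd_run(cfg, interaction_table(), steps = 200, sample_period = 100,
#'               seed = 1)
#' length(tr$frames)  # 2
#' }
#' @export
dpd_run <- function(config, interactions, steps, pre_equil_steps = 0,
                    sample_period = 100, dt = 0.05, lambda = 0.65,
                    seed = 1, log_period = sample_period) {
  stopifnot(inherits(config, "dpd_config"),
            inherits(interactions, "dpd_interactions"),
            steps >= 0, pre_equil_steps >= 0, sample_period >= 1, dt > 0)
  if (!fdt_balanced(interactions)) {
    rlang::abort(paste0(
      "dissipative and random forces are unbalanced: need sigma^2 = 2 gamma kT",
      sprintf(" (sigma = %g, gamma = %g)", interactions$sigma, interactions$gamma)
    ))
  }
  box <- config_box(config)
  chain <- config_chain(config) %||% chain_spec()
  bonds <- config_bonds(config)
  res <- cpp_dpd_run(
    pos = cbind(config$x, config$y, config$z),
    vel = cbind(config$vx, config$vy, config$vz),
    species = species_code(config$species),
    frozen = config$frozen,
    bond_i = bonds$i, bond_j = bonds$j,
    K = chain$K, r0 = chain$r0,
    a = unname(interactions$a), gamma = interactions$gamma,
    sigma = interactions$sigma,
    box = box_for_cpp(box), dt = dt, lambda = lambda,
    pre_steps = as.integer(pre_equil_steps), steps = as.integer(steps),
    sample_period = as.integer(sample_period),
    log_period = as.integer(log_period), seed = as.double(seed)
  )
  frames <- lapply(res$frames, function(fr) {
    beads <- config
    beads$x <- fr$pos[, 1]; beads$y <- fr$pos[, 2]; beads$z <- fr$pos[, 3]
    beads$vx <- fr$vel[, 1]; beads$vy <- fr$vel[, 2]; beads$vz <- fr$vel[, 3]
    attr(beads, "time") <- as.integer(fr$step)
    beads
  })
  log <- tibble::tibble(step = res$log[, 1], kT = res$log[, 2],
                        px = res$log[, 3], py = res$log[, 4],
                        pz = res$log[, 5])
  structure(
    list(frames = frames, log = log, overlaps = res$overlaps,
         params = list(steps = steps, pre_equil_steps = pre_equil_steps,
                       sample_period = sample_period, dt = dt,
                       lambda = lambda, seed = seed,
                       interactions = interactions, box = box,
                       chain = chain)),
    class = "dpd_trajectory"
  )
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  cat(sprintf(
    "<dpd_trajectory> %d frames of %d beads; %d + %d steps, dt = %g, seed = %s\n",
    length(x$frames), if (length(x$frames)) nrow(x$frames[[1]]) else 0L,
    x$params$pre_equil_steps, x$params$steps, x$params$dt,
    format(x$params$seed)))
  invisible(x)
}

#' Tidy the run log of a trajectory
#'
#' @param x A `dpd_trajectory`.
#' @param ... Unused.
#' @return Tibble with `step`, instantaneous `kT` and total momentum
#'   components `px`, `py`, `pz`.
#' @export
tidy.dpd_trajectory <- function(x, ...) x$log

#' One-row summary of a trajectory run
#'
#' @param x A `dpd_trajectory`.
#' @param ... Unused.
#' @return Tibble with frame count, mean and sd of instantaneous kT over
#'   the production part, maximum |total momentum| per mobile bead, and
#'   the coincident-pair counter.
#' @export
glance.dpd_trajectory <- function(x, ...) {
  prod_log <- dplyr::filter(x$log, .data$step > x$params$pre_equil_steps)
  if (!nrow(prod_log)) prod_log <- x$log
  n_mobile <- if (length(x$frames)) sum(!x$frames[[1]]$frozen) else NA_integer_
  tibble::tibble(
    n_frames = length(x$frames),
    kT_mean = mean(prod_log$kT),
    kT_sd = stats::sd(prod_log$kT),
    max_momentum_per_bead = max(sqrt(prod_log$px^2 + prod_log$py^2 +
                                       prod_log$pz^2)) / n_mobile,
    overlaps = x$overlaps
  )
}
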
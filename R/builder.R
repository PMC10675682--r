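# Initial-configuration builders.  A configuration is a tibble with one
# row per bead and the box / chain architecture attached as attributes,
# so every analysis verb can take it as its first argument and pipe.

#' Construct a configuration tibble
#'
#' Low-level constructor; most users will call [build_bulk()],
#' [build_slit()] or one of the planted-fixture generators instead.
#'
#' @param beads A data frame with columns `species` (character, one of
#'   A/B/S/W), `x`, `y`, `z`, `vx`, `vy`, `vz`, `chain_id` (integer; -1
#'   for solvent and wall beads) and `frozen` (logical, TRUE only for W).
#' @param box A `dpd_box`.
#' @param chain A `dpd_chain` describing the copolymer architecture, or
#'   `NULL` for chain-free systems.
#' @param time Step index of the snapshot.
#' @return A tibble of class `dpd_config`.
#' @export
dpd_config <- function(beads, box, chain = NULL, time = 0L) {
  req <- c("species", "x", "y", "z", "vx", "vy", "vz", "chain_id", "frozen")
  missing_cols <- setdiff(req, names(beads))
  if (length(missing_cols)) {
    rlang::abort(paste0("configuration lacks columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!all(beads$species %in% DPD_SPECIES)) {
    rlang::abort("species must be one of A, B, S, W")
  }
  out <- tibble::as_tibble(beads[req])
  out[] <- lapply(out, unname)
  out$chain_id <- as.integer(out$chain_id)
  attr(out, "box") <- box
  attr(out, "chain") <- chain
  attr(out, "time") <- as.integer(time)
  class(out) <- c("dpd_config", class(out))
  out
}

#' @export
print.dpd_config <- function(x, ...) {
  box <- config_box(x)
  n_ch <- n_chains(x)
  cat(sprintf("<dpd_config> %d beads (%d chains), %s box %g x %g x %g, step %d\n",
              nrow(x), n_ch, box$kind, box$Lx, box$Ly, box$Lz,
              attr(x, "time") %||% 0L))
  NextMethod()
}

#' @rdname dpd_config
#' @param config A `dpd_config`.
#' @export
config_box <- function(config) attr(config, "box")

#' @rdname dpd_config
#' @export
config_chain <- function(config) attr(config, "chain")

#' Number of copolymer chains in a configuration
#' @param config A `dpd_config`.
#' @return Integer count of distinct chain ids (solvent/wall excluded).
#' @export
n_chains <- function(config) {
  length(unique(config$chain_id[config$chain_id >= 0]))
}

maxwell_velocities <- function(n, kT = 1) {
  matrix(stats::rnorm(3 * n, sd = sqrt(kT)), ncol = 3)
}

# Freely-jointed random walk of `n` beads with fixed step, starting at
# `origin`; slit walks are reflected back through the planes so every
# bead satisfies |x| < D/2.
random_walk_chain <- function(n, origin, step, box) {
  dirs <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2)) * step
  pos <- apply(rbind(origin, dirs), 2, cumsum)
  if (box$kind == "slit") {
    half <- box$D / 2
    # reflect into (-half, half)
    x <- pos[, 1]
    x <- abs((x + half) %% (2 * box$D))
    x <- ifelse(x > box$D, 2 * box$D - x, x) - half
    # keep strictly inside
    eps <- 1e-6
    pos[, 1] <- pmin(pmax(x, -half + eps), half - eps)
  } else {
    pos[, 1] <- pos[, 1] %% box$Lx
  }
  pos[, 2] <- pos[, 2] %% box$Ly
  pos[, 3] <- pos[, 3] %% box$Lz
  pos
}

build_polymer_beads <- function(n_chains, chain, box, step = 0.5) {
  if (n_chains == 0) {
    return(tibble::tibble(species = character(), x = numeric(), y = numeric(),
                          z = numeric(), chain_id = integer()))
  }
  half <- if (box$kind == "slit") box$D / 2 else box$Lx
  origins <- cbind(
    if (box$kind == "slit") stats::runif(n_chains, -half + 0.5, half - 0.5)
    else stats::runif(n_chains, 0, box$Lx),
    stats::runif(n_chains, 0, box$Ly),
    stats::runif(n_chains, 0, box$Lz)
  )
  pieces <- lapply(seq_len(n_chains), function(i) {
    pos <- random_walk_chain(chain$n, origins[i, ], step, box)
    tibble::tibble(species = chain$species,
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   chain_id = i - 1L)
  })
  dplyr::bind_rows(pieces)
}

solvent_beads <- function(n, box) {
  if (n <= 0) {
    return(tibble::tibble(species = character(), x = numeric(), y = numeric(),
                          z = numeric(), chain_id = integer()))
  }
  x <- if (box$kind == "slit") {
    stats::runif(n, -box$D / 2 + 1e-6, box$D / 2 - 1e-6)
  } else {
    stats::runif(n, 0, box$Lx)
  }
  tibble::tibble(species = "S", x = x,
                 y = stats::runif(n, 0, box$Ly),
                 z = stats::runif(n, 0, box$Lz),
                 chain_id = -1L)
}

finish_config <- function(poly, solv, wall, box, chain, kT = 1) {
  mobile <- dplyr::bind_rows(poly, solv)
  v <- maxwell_velocities(nrow(mobile), kT)
  v <- sweep(v, 2, colMeans(v))  # zero total momentum
  mobile$vx <- v[, 1]; mobile$vy <- v[, 2]; mobile$vz <- v[, 3]
  mobile$frozen <- FALSE
  if (!is.null(wall) && nrow(wall)) {
    wall$vx <- wall$vy <- wall$vz <- 0
    wall$frozen <- TRUE
    mobile <- dplyr::bind_rows(mobile, wall)
  }
  dpd_config(mobile, box, chain)
}

#' Build a bulk copolymer solution
#'
#' Places `n_chains` copolymers as freely-jointed random walks (step
#' 0.5 r_c; the soft DPD potentials tolerate the resulting overlaps,
#' which pre-equilibration erases) and fills the remainder of
#' `round(rho * V)` beads with solvent.  Velocities are drawn from the
#' Maxwell distribution at kT = 1 and shifted to zero total momentum.
#'
#' @param n_chains Number of copolymer chains.
#' @param chain A `dpd_chain` (default [chain_spec()]).
#' @param box A bulk `dpd_box` (default [bulk_box()]).
#' @param rho Overall bead number density (default 3).
#' @param seed RNG seed; same seed gives an identical configuration.
#' @return A `dpd_config` tibble.
#' @examples
#' cfg <- build_bulk(10, box = bulk_box(6), seed = 1)
#' nrow(cfg)  # round(3 * 6^3) = 648
#' @export
build_bulk <- function(n_chains, chain = chain_spec(), box = bulk_box(),
                       rho = 3, seed = 1) {
  stopifnot(box$kind == "bulk", n_chains >= 0)
  total <- round(rho * box_volume(box))
  n_poly <- n_chains * chain$n
  if (n_poly > total) {
    rlang::abort(sprintf("overfull box: %d polymer beads exceed rho*V = %d",
                         n_poly, total))
  }
  withr::local_seed(seed)
  poly <- build_polymer_beads(n_chains, chain, box)
  solv <- solvent_beads(total - n_poly, box)
  finish_config(poly, solv, NULL, box, chain)
}

#' Frozen wall-bead layer for a slit
#'
#' One slab of thickness 1 r_c immediately outside each reflecting plane
#' (`D/2 < |x| <= D/2 + 1`), filled with wall beads at density
#' `rho_wall`, uniformly at random and frozen for the whole run.  A
#' single one-cutoff slab suffices because every pair force vanishes
#' beyond r_c.
#'
#' @param box A slit `dpd_box`.
#' @param rho_wall Wall-bead number density (default 3, matching the
#'   fluid); 0 gives a bare reflecting wall with only the soft potential.
#' @param seed RNG seed.
#' @return Tibble of wall beads (species `W`, `chain_id = -1`).
#' @export
make_wall_layer <- function(box, rho_wall = 3, seed = 1) {
  stopifnot(box$kind == "slit", rho_wall >= 0)
  n_side <- round(rho_wall * 1 * box$Ly * box$Lz)
  if (n_side == 0) {
    return(tibble::tibble(species = character(), x = numeric(), y = numeric(),
                          z = numeric(), chain_id = integer()))
  }
  withr::local_seed(seed)
  half <- box$D / 2
  x <- c(stats::runif(n_side, -half - 1, -half), stats::runif(n_side, half, half + 1))
  # exclusive at the plane itself, inclusive at the outer edge
  x <- ifelse(abs(x) <= half, sign(x) * (half + 1e-9), x)
  tibble::tibble(species = "W", x = x,
                 y = stats::runif(2 * n_side, 0, box$Ly),
                 z = stats::runif(2 * n_side, 0, box$Lz),
                 chain_id = -1L)
}

#' Build a confined copolymer solution in a slit
#'
#' Mobile beads (`round(rho * D * Ly * Lz)` in total) are placed between
#' the reflecting planes at `x = -D/2` and `x = +D/2`; frozen wall beads
#' are added just outside both planes via [make_wall_layer()].
#'
#' @inheritParams build_bulk
#' @param box A slit `dpd_box` from [slit_box()].
#' @param rho_wall Density of the frozen wall-bead slabs (default 3).
#' @return A `dpd_config` tibble.
#' @export
build_slit <- function(n_chains, chain = chain_spec(), box, rho = 3,
                       rho_wall = 3, seed = 1) {
  stopifnot(inherits(box, "dpd_box"), box$kind == "slit")
  if (box$D < 4) rlang::abort("slit too narrow: D must be at least 4 r_c")
  total <- round(rho * box_volume(box))
  n_poly <- n_chains * chain$n
  if (n_poly > total) {
    rlang::abort(sprintf("overfull slit: %d polymer beads exceed rho*V = %d",
                         n_poly, total))
  }
  withr::local_seed(seed)
  poly <- build_polymer_beads(n_chains, chain, box)
  solv <- solvent_beads(total - n_poly, box)
  wall <- make_wall_layer(box, rho_wall, seed = seed + 1L)
  finish_config(poly, solv, wall, box, chain)
}
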
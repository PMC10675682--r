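# Model parameters, reduced units, Flory-Huggins mapping, concentration
# arithmetic.  All internal computation uses DPD reduced units:
# r_c = kT = m0 = 1, tau = sqrt(m0 r_c^2 / kT).

DPD_SPECIES <- c("A", "B", "S", "W")

#' Reduced DPD unit system
#'
#' All lengths are measured in the interaction cutoff `r_c`, energies in
#' `kT` and masses in the bead mass `m0`; the derived time unit is
#' `tau = sqrt(m0 * r_c^2 / kT)`.  Internally every one of the base units
#' is 1; this constructor exists to make the convention explicit and to
#' carry the integration timestep.
#'
#' @param dt Timestep in units of `tau` (default 0.05).
#' @return A list with class `dpd_units` holding `r_c`, `kT`, `m0`, `tau`
#'   and `dt`.
#' @examples
#' reduced_units()$tau  # 1
#' @export
reduced_units <- function(dt = 0.05) {
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0)
  structure(
    list(r_c = 1, kT = 1, m0 = 1, tau = 1, dt = dt),
    class = "dpd_units"
  )
}

#' Pairwise soft-repulsion table for the four bead species
#'
#' Builds the symmetric species-by-species matrix of maximum conservative
#' repulsions `a_ij` for species A (soluble block), B (insoluble block),
#' S (solvent) and W (wall beads), together with the friction coefficient
#' `gamma` and noise amplitude `sigma` of the DPD thermostat.  The noise
#' amplitude must satisfy the fluctuation-dissipation balance
#' `sigma^2 = 2 * gamma * kT`; with the conventional `gamma = 4.5` and
#' `kT = 1` this gives `sigma = 3` exactly.
#'
#' The defaults describe an A5B5 copolymer in a selective solvent: all
#' compatible pairs at the athermal baseline 25 (`chi = 0` at bead density
#' 3), and strongly unfavorable B--solvent and A--B contacts at 40
#' (`chi` of about 4.59).  The wall affinity is controlled solely through
#' `a_BW`; four standard wall scenarios are provided via `wall`:
#' `"repulsive"` (a_BW = 30), `"inert"` (25), `"weak_attract"` (20) and
#' `"strong_attract"` (15).
#'
#' @param a Optional named list of overrides for individual pairs, e.g.
#'   `list(BW = 18, AB = 38)`.  Pair names are unordered ("BW" == "WB").
#' @param gamma Friction coefficient (default 4.5).
#' @param sigma Noise amplitude; default `sqrt(2 * gamma)`, i.e. 3 for the
#'   default `gamma`.
#' @param wall One of `"repulsive"`, `"inert"`, `"weak_attract"`,
#'   `"strong_attract"`; sets `a_BW` before `a` overrides are applied.
#' @return An object of class `dpd_interactions`: a list with the 4x4
#'   symmetric matrix `a` (rows/cols A, B, S, W), `gamma` and `sigma`.
#' @examples
#' it <- interaction_table(wall = "strong_attract")
#' it$a["B", "W"]  # 15
#' @export
interaction_table <- function(a = NULL, gamma = 4.5, sigma = sqrt(2 * gamma),
                              wall = c("inert", "repulsive", "weak_attract",
                                       "strong_attract")) {
  wall <- match.arg(wall)
  m <- matrix(25, 4, 4, dimnames = list(DPD_SPECIES, DPD_SPECIES))
  m["A", "B"] <- m["B", "A"] <- 40
  m["B", "S"] <- m["S", "B"] <- 40
  a_bw <- switch(wall,
    repulsive = 30, inert = 25, weak_attract = 20, strong_attract = 15
  )
  m["B", "W"] <- m["W", "B"] <- a_bw
  if (!is.null(a)) {
    stopifnot(is.list(a), rlang::is_named(a))
    for (nm in names(a)) {
      sp <- strsplit(nm, "")[[1]]
      if (length(sp) != 2 || !all(sp %in% DPD_SPECIES)) {
        rlang::abort(sprintf("unknown species pair '%s'", nm))
      }
      val <- a[[nm]]
      stopifnot(is.numeric(val), length(val) == 1, val >= 0)
      m[sp[1], sp[2]] <- m[sp[2], sp[1]] <- val
    }
  }
  if (any(m < 0)) rlang::abort("repulsion parameters must be non-negative")
  stopifnot(is.numeric(gamma), gamma >= 0, is.numeric(sigma), sigma >= 0)
  structure(
    list(a = m, gamma = gamma, sigma = sigma, wall = wall),
    class = "dpd_interactions"
  )
}

#' Check the fluctuation-dissipation balance of an interaction table
#'
#' The dissipative and random forces thermostat the system only when
#' `sigma^2 = 2 * gamma * kT`.  The engine refuses unbalanced tables;
#' this predicate is exported so configurations can be validated early.
#'
#' @param interactions A `dpd_interactions` object.
#' @param kT Target temperature (1 in reduced units).
#' @param tol Relative tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
fdt_balanced <- function(interactions, kT = 1, tol = 1e-12) {
  abs(interactions$sigma^2 - 2 * interactions$gamma * kT) <= tol * max(1, 2 * interactions$gamma * kT)
}

#' Diblock chain architecture
#'
#' Describes a linear flexible copolymer as ordered blocks of beads joined
#' by harmonic springs with energy `U = (K/2) (r - r0)^2` (so the force
#' magnitude is `K * |r - r0|`).  The default is the symmetric A5B5 chain:
#' five soluble A beads followed by five insoluble B beads, `K = 4`,
#' `r0 = 0`.  Users whose convention is `U = K (r - r0)^2` should double
#' `K`.
#'
#' @param blocks Named integer vector of block run-lengths in chain order,
#'   names in `A`, `B`, `S` (default `c(A = 5, B = 5)`).
#' @param K Spring constant (energy / length^2).
#' @param r0 Equilibrium bond length (default 0: bonded beads are pulled
#'   toward coincidence, which the soft non-diverging repulsion permits).
#' @return A `dpd_chain` list with `blocks`, `species` (per-bead label
#'   vector), `n` (beads per chain), `K`, `r0`.
#' @examples
#' chain_spec()$n  # 10
#' @export
chain_spec <- function(blocks = c(A = 5L, B = 5L), K = 4, r0 = 0) {
  stopifnot(length(blocks) >= 1, all(blocks >= 1),
            all(names(blocks) %in% c("A", "B", "S")),
            K > 0, r0 >= 0)
  species <- rep(names(blocks), times = blocks)
  structure(
    list(blocks = blocks, species = species, n = length(species),
         K = K, r0 = r0),
    class = "dpd_chain"
  )
}

#' Cubic bulk simulation box
#'
#' Periodic in all three directions.
#'
#' @param L Edge length (default 25 r_c).
#' @return A `dpd_box` list.
#' @export
bulk_box <- function(L = 25) {
  stopifnot(L > 0)
  structure(
    list(kind = "bulk", Lx = L, Ly = L, Lz = L,
         periodic = c(x = TRUE, y = TRUE, z = TRUE)),
    class = "dpd_box"
  )
}

#' Slit simulation box
#'
#' Two parallel walls perpendicular to the x axis: hard reflecting planes
#' at `x = -D/2` and `x = +D/2`, supplemented by a short-range soft
#' repulsive wall potential of amplitude `a_wall` and range `x_c`, and by
#' layers of frozen wall beads just outside the planes.  Periodic in y
#' and z only.  The slit volume used for concentrations is `D * Ly * Lz`.
#'
#' @param D Distance between the reflecting planes (typically 10--25 r_c).
#' @param Ly,Lz Lateral box lengths (default 25).
#' @param x_c Range of the soft wall repulsion (default 1.2, which
#'   suppresses density oscillations next to the wall).
#' @param a_wall Amplitude of the soft wall potential, applied equally to
#'   every mobile species (default 25).  Species-selective wall affinity
#'   acts only through the frozen wall beads (pair entry `a_BW` etc.).
#' @return A `dpd_box` list.
#' @export
slit_box <- function(D, Ly = 25, Lz = 25, x_c = 1.2, a_wall = 25) {
  stopifnot(D > 0, Ly > 0, Lz > 0, x_c > 0, a_wall >= 0)
  if (D <= 2 * x_c) {
    rlang::abort("slit width D must exceed twice the wall repulsion range x_c")
  }
  structure(
    list(kind = "slit", Lx = D, Ly = Ly, Lz = Lz, D = D,
         x_c = x_c, a_wall = a_wall,
         periodic = c(x = FALSE, y = TRUE, z = TRUE)),
    class = "dpd_box"
  )
}

#' Box volume used for concentrations
#'
#' For a slit this is `D * Ly * Lz`, the volume between the reflecting
#' planes (wall-bead slabs excluded).
#'
#' @param box A `dpd_box`.
#' @return Volume in r_c^3.
#' @export
box_volume <- function(box) {
  stopifnot(inherits(box, "dpd_box"))
  box$Lx * box$Ly * box$Lz
}

#' Map a Flory-Huggins parameter to a DPD repulsion
#'
#' The Groot-Warren correspondence for a soft repulsive DPD fluid at bead
#' density `rho r_c^3 = 3`, matched to the compressibility of ambient
#' water, is linear:
#'
#'   a_ij = a_ii + 3.27 * chi_ij     (in kT / r_c)
#'
#' so the athermal state chi = 0 maps to a_ij = a_ii = 25, the theta
#' state chi = 1/2 to a_ij = 26.64, and a_ij = 40 to a strongly
#' unfavorable chi of about 4.59.
#'
#' @param chi Flory-Huggins interaction parameter (any real; values below
#'   zero describe net attraction).
#' @param a_ii Like-pair baseline repulsion (default 25).
#' @return Repulsion `a_ij` in kT / r_c; vectorized over `chi`.
#' @examples
#' chi_to_a(0.5)  # 26.635
#' @export
chi_to_a <- function(chi, a_ii = 25) {
  stopifnot(is.numeric(chi), is.numeric(a_ii), all(a_ii >= 0))
  a_ii + 3.27 * chi
}

#' Invert the Flory-Huggins / repulsion mapping
#'
#' @param a_ij Cross-pair repulsion.
#' @param a_ii Like-pair baseline (default 25).
#' @return `chi = (a_ij - a_ii) / 3.27`; the exact inverse of
#'   [chi_to_a()].
#' @examples
#' a_to_chi(40)  # 4.587...
#' @export
a_to_chi <- function(a_ij, a_ii = 25) {
  stopifnot(is.numeric(a_ij), is.numeric(a_ii))
  (a_ij - a_ii) / 3.27
}

#' Volume concentration of copolymer in percent
#'
#' Because DPD beads are soft and interpenetrate at bead densities above
#' 1, the volume concentration is defined relative to the applied density:
#' `c = 100 * N * n / (rho * V)` where `N` is the number of chains, `n`
#' the beads per chain, `rho` the overall bead density and `V` the box
#' volume (slit: `D * Ly * Lz`).
#'
#' @param n_chains Number of copolymer chains `N`.
#' @param beads_per_chain Beads per chain `n` (default 10 for A5B5).
#' @param rho Overall bead number density (default 3).
#' @param volume Box volume, e.g. `box_volume(bulk_box())`.
#' @return Concentration in percent.
#' @examples
#' concentration(300, volume = 25^3)  # 6.4
#' @export
concentration <- function(n_chains, beads_per_chain = 10, rho = 3, volume) {
  stopifnot(all(n_chains >= 0), beads_per_chain > 0)
  if (any(volume <= 0) || any(rho <= 0)) {
    rlang::abort("invalid geometry: rho and volume must be positive")
  }
  100 * n_chains * beads_per_chain / (rho * volume)
}

#' Number of chains realizing a target concentration
#'
#' Inverts [concentration()] and rounds to the nearest whole chain; the
#' realized concentration is then within one chain's worth of the target.
#' A warning is issued when the target is not exactly representable.
#'
#' @inheritParams concentration
#' @param c_percent Target concentration in percent.
#' @param quiet Suppress the rounding warning.
#' @return Integer chain count.
#' @examples
#' chains_for_concentration(6.4, volume = 25^3)  # 300
#' @export
chains_for_concentration <- function(c_percent, beads_per_chain = 10, rho = 3,
                                     volume, quiet = FALSE) {
  stopifnot(c_percent >= 0, volume > 0, rho > 0)
  exact <- c_percent * rho * volume / (100 * beads_per_chain)
  n <- as.integer(round(exact))
  if (!quiet && abs(exact - n) > 1e-9) {
    rlang::warn(sprintf(
      "concentration %.4g%% not exactly representable; using %d chains (c = %.4g%%)",
      c_percent, n, concentration(n, beads_per_chain, rho, volume)
    ))
  }
  n
}

#' Chain capacity of a cylinder relative to a string of spheres
#'
#' A cylindrical micelle core of diameter `D` and length `N * D` has
#' volume `pi D^2/4 * N D`, while `N` spherical cores of diameter `D`
#' have total volume `N * pi D^3 / 6`; the ratio is 3/2 regardless of `N`
#' and `D`.  At fixed core density this is the factor by which a rod-like
#' associate out-accommodates the equivalent string of spherical
#' micelles, one driver of the sphere-to-rod crossover at elevated
#' concentration.
#'
#' @param n_spheres Number of spheres `N` (>= 1).
#' @return The capacity ratio, always 1.5.
#' @export
cylinder_sphere_capacity_ratio <- function(n_spheres) {
  if (any(n_spheres < 1)) rlang::abort("n_spheres must be at least 1")
  # computed, not hard-coded: cylinder volume over N sphere volumes for D = 1
  d <- 1
  cyl <- pi * d^2 / 4 * (n_spheres * d)
  sph <- n_spheres * pi * d^3 / 6
  cyl / sph
}
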
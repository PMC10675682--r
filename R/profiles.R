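# Binned number-density profiles across slits and along arbitrary
# directions, wall coverage, and density-layer counting.

traj_frames <- function(trajectory) {
  fr <- if (inherits(trajectory, "dpd_trajectory")) trajectory$frames
        else if (inherits(trajectory, "dpd_config")) list(trajectory)
        else trajectory
  if (!length(fr)) rlang::abort("trajectory has no frames")
  fr
}

new_density_profile <- function(tbl, axis, bin_width, frames) {
  attr(tbl, "axis") <- axis
  attr(tbl, "bin_width") <- bin_width
  attr(tbl, "frames_averaged") <- frames
  class(tbl) <- c("density_profile", class(tbl))
  tbl
}

#' Density profile across a slit
#'
#' Histograms the x coordinate of mobile beads of the requested species
#' over all frames and converts counts to number densities by the slab
#' volume `bin_width * Ly * Lz` and the number of frames, so the
#' integral of each species profile equals its mean per-frame bead
#' count.
#'
#' @param trajectory A `dpd_trajectory`, list of frames, or single
#'   `dpd_config` (slit geometry).
#' @param species Species to profile (default `"B"`, the core-forming
#'   beads; several allowed).
#' @param bin_width Bin width along x (default 0.25 r_c, fine enough to
#'   resolve micelle-scale structure).
#' @return A `density_profile` tibble: `x` (bin center), `species`,
#'   `density` (beads / r_c^3).
#' @export
slit_profile <- function(trajectory, species = "B", bin_width = 0.25) {
  frames <- traj_frames(trajectory)
  box <- config_box(frames[[1]])
  if (box$kind != "slit") rlang::abort("slit_profile needs a slit trajectory")
  if (bin_width > box$D) rlang::abort("bin_width exceeds the slit width")
  half <- box$D / 2
  nb <- ceiling(box$D / bin_width)
  edges <- seq(-half, by = bin_width, length.out = nb + 1)
  area <- box$Ly * box$Lz
  out <- purrr::map_dfr(species, function(sp) {
    counts <- numeric(nb)
    for (cfg in frames) {
      xs <- cfg$x[cfg$species == sp & !cfg$frozen]
      xs <- xs[xs >= -half & xs <= half]
      idx <- pmin(pmax(floor((xs + half) / bin_width) + 1, 1), nb)
      counts <- counts + tabulate(idx, nbins = nb)
    }
    tibble::tibble(x = (edges[-1] + edges[-(nb + 1)]) / 2, species = sp,
                   density = counts / (length(frames) * bin_width * area))
  })
  new_density_profile(out, "x", bin_width, length(frames))
}

#' Density scan along an arbitrary direction
#'
#' Bins bead positions on their projection onto a unit direction,
#' folding the projected coordinate onto one period of the projected
#' box.  Oscillations along the scan direction reveal layered or
#' lamellar ordering that an isotropic average would wash out; scanning
#' several directions locates the orientation of partial ordering in
#' bulk systems.
#'
#' For periodic directions the fold period is the shortest projection of
#' a box lattice vector onto the direction.  In slits the direction must
#' be either the x axis (equivalent to [slit_profile()]) or lie in the
#' periodic y-z plane.
#'
#' @param trajectory A trajectory or configuration.
#' @param direction Length-3 direction vector (normalized internally).
#' @param species Species to profile (default `"B"`).
#' @param bin_width Bin width along the projection (default 0.25).
#' @return A `density_profile` tibble: `s` (projected coordinate bin
#'   center), `species`, `density`.
#' @export
directional_scan <- function(trajectory, direction, species = "B",
                             bin_width = 0.25) {
  frames <- traj_frames(trajectory)
  box <- config_box(frames[[1]])
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) rlang::abort("direction must be a non-zero vector")
  u <- direction / nrm
  if (box$kind == "slit") {
    if (abs(u[1]) > 1e-9 && (abs(u[2]) > 1e-9 || abs(u[3]) > 1e-9)) {
      rlang::abort("in slits the scan direction must be the x axis or lie in the y-z plane")
    }
    if (abs(u[1]) > 1e-9) {
      pr <- slit_profile(frames, species, bin_width)
      out <- dplyr::rename(tibble::as_tibble(pr), s = "x")
      return(new_density_profile(out, u, bin_width, length(frames)))
    }
  }
  L <- c(if (box$kind == "bulk") box$Lx else box$D, box$Ly, box$Lz)
  per <- which(box$periodic & abs(u) > 1e-12)
  # fold period: shortest projected box lattice vector among periodic axes
  period <- min(L[per] * abs(u[per]))
  nb <- max(1, round(period / bin_width))
  bw <- period / nb  # exact tiling of one period
  vol_bin <- prod(L) / period * bw
  out <- purrr::map_dfr(species, function(sp) {
    counts <- numeric(nb)
    for (cfg in frames) {
      sel <- cfg$species == sp & !cfg$frozen
      s <- (cfg$x[sel] * u[1] + cfg$y[sel] * u[2] + cfg$z[sel] * u[3]) %% period
      idx <- pmin(floor(s / bw) + 1, nb)
      counts <- counts + tabulate(idx, nbins = nb)
    }
    tibble::tibble(s = (seq_len(nb) - 0.5) * bw, species = sp,
                   density = counts / (length(frames) * vol_bin))
  })
  new_density_profile(out, u, bw, length(frames))
}

#' Wall coverage by core beads
#'
#' Mean number of B beads within `width` of each reflecting plane,
#' divided by the wall area `Ly * Lz`: the adsorbed surface
#' concentration `rho_c` per wall.
#'
#' @param trajectory A slit trajectory or configuration.
#' @param width Thickness of the adsorbed layer counted (default 1 r_c,
#'   matching the wall-contact rule).
#' @param species Species counted (default `"B"`).
#' @return Tibble with `wall` (`"lower"` at `x = -D/2`, `"upper"` at
#'   `x = +D/2`) and `rho_c` (beads / r_c^2).
#' @export
wall_coverage <- function(trajectory, width = 1, species = "B") {
  frames <- traj_frames(trajectory)
  box <- config_box(frames[[1]])
  if (box$kind != "slit") rlang::abort("wall_coverage needs a slit trajectory")
  if (width > box$D / 2) rlang::abort("adsorbed-layer width exceeds D/2")
  half <- box$D / 2
  area <- box$Ly * box$Lz
  lower <- upper <- 0
  for (cfg in frames) {
    xs <- cfg$x[cfg$species %in% species & !cfg$frozen]
    lower <- lower + sum(xs <= -half + width & xs >= -half)
    upper <- upper + sum(xs >= half - width & xs <= half)
  }
  tibble::tibble(wall = c("lower", "upper"),
                 rho_c = c(lower, upper) / (length(frames) * area))
}

# interior local maxima of a numeric vector with their prominences: for
# each peak, walk outward over all terrain not higher than the peak; each
# side's base is the lowest point passed (boundary inclusive when no
# higher ground is met), and the prominence is the peak height minus the
# higher of the two bases.  Boundary samples cannot themselves be peaks.
peak_prominences <- function(s) {
  n <- length(s)
  if (n < 3) return(list(peaks = integer(), prominence = numeric()))
  left <- c(Inf, s[-n])
  right <- c(s[-1], -Inf)
  peaks <- setdiff(which(s > left & s >= right), c(1L, n))
  side_base <- function(i, step) {
    lo <- s[i]
    j <- i
    while (j + step >= 1 && j + step <= n && s[j + step] <= s[i]) {
      j <- j + step
      lo <- min(lo, s[j])
    }
    lo
  }
  prom <- vapply(peaks, function(i) {
    s[i] - max(side_base(i, -1L), side_base(i, 1L))
  }, numeric(1))
  list(peaks = peaks, prominence = prom)
}

#' Count density layers in a profile
#'
#' Layered ordering shows up as local maxima of the (smoothed) density
#' profile.  A maximum counts as a layer when its prominence -- its
#' height over the higher of its two key saddles -- exceeds a stated
#' fraction of the profile maximum, so sampling ripple is ignored.  A
#' flat or monotone profile has zero layers.
#'
#' @param profile A `density_profile` (single species) or numeric vector
#'   of densities on a uniform grid.
#' @param prominence Minimum peak prominence as a fraction of the
#'   profile maximum (default 0.1).
#' @param smooth_window Odd moving-average window (default 3).
#' @return Integer layer count.
#' @export
layer_count <- function(profile, prominence = 0.1, smooth_window = 3) {
  y <- if (is.numeric(profile)) profile else {
    if (length(unique(profile$species)) > 1) {
      rlang::abort("layer_count expects a single-species profile")
    }
    profile$density
  }
  s <- moving_average(y, smooth_window)
  if (max(s) <= 0 || diff(range(s)) < 1e-12) return(0L)
  pk <- peak_prominences(s)
  sum(pk$prominence >= prominence * max(s))
}
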
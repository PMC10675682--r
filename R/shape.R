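# Gyration-tensor shape analysis of aggregate cores (B beads) and whole
# aggregates (A + B).

#' Unwrap an aggregate across periodic boundaries
#'
#' Periodic wrapping tears an aggregate that straddles a box face into
#' pieces, which would wreck any second-moment analysis.  The beads are
#' made whole again by a breadth-first traversal of their proximity
#' graph (minimum-image distance below `cutoff`): each newly reached
#' bead is placed at its minimum image relative to its already-unwrapped
#' neighbor.  The result is unique up to a global translation provided
#' the aggregate spans less than half the box in every periodic
#' direction; wider aggregates are flagged with a warning because their
#' unwrap is ambiguous.
#'
#' @param config A `dpd_config`.
#' @param chain_ids Chains forming one aggregate.
#' @param species Bead species to keep (default A and B).
#' @param cutoff Adjacency distance for the traversal (default 1.3 r_c:
#'   generous enough to bridge bonds and core contacts).
#' @return Matrix of unwrapped coordinates (one row per kept bead), with
#'   attributes `species`, `n_components` and `ambiguous`.
#' @export
unwrap_aggregate <- function(config, chain_ids, species = c("A", "B"),
                             cutoff = 1.3) {
  box <- config_box(config)
  sel <- config$chain_id %in% chain_ids & config$species %in% species
  if (!any(sel)) rlang::abort("no beads selected")
  L <- c(if (box$kind == "bulk") box$Lx else box$D, box$Ly, box$Lz)
  res <- cpp_unwrap(cbind(config$x[sel], config$y[sel], config$z[sel]),
                    boxlen = L, periodic = unname(box$periodic),
                    cutoff = cutoff)
  if (res$ambiguous) {
    rlang::warn("aggregate spans more than half the box; unwrap is ambiguous")
  }
  structure(res$pos, species = config$species[sel],
            n_components = res$n_components, ambiguous = res$ambiguous)
}

#' Gyration tensor size parameters
#'
#' The gyration tensor `S = (1/N) sum (r_i - rbar)(r_i - rbar)^T` of a
#' set of (unwrapped, unit-mass) bead positions.  Its eigenvalues,
#' sorted ascending as `lambda1^2 <= lambda2^2 <= lambda3^2`, are the
#' squared size parameters along the principal axes; their sum is the
#' squared radius of gyration.  A sphere has three comparable
#' eigenvalues; a rod has one dominant.  `mode = "diagonal"` instead
#' returns the lab-frame diagonal entries (sorted ascending), which is
#' basis-dependent and only meaningful when the frame is physically
#' distinguished.
#'
#' @param positions Numeric matrix (or data frame with columns x, y, z)
#'   of bead positions; must already be unwrapped.
#' @param mode `"eigen"` (default) or `"diagonal"`.
#' @return List of class `gyration` with `lambda_sq` (ascending), and
#'   `rg_sq` (their sum).
#' @examples
#' g <- gyration(rbind(c(0, 0, 0), c(0, 0, 2)))
#' g$lambda_sq  # 0 0 1  (two points d apart: (0, 0, d^2/4))
#' @export
gyration <- function(positions, mode = c("eigen", "diagonal")) {
  mode <- match.arg(mode)
  if (is.data.frame(positions)) {
    positions <- cbind(positions$x, positions$y, positions$z)
  }
  stopifnot(is.matrix(positions), ncol(positions) == 3, nrow(positions) >= 1)
  ctr <- sweep(positions, 2, colMeans(positions))
  S <- crossprod(ctr) / nrow(positions)
  lam <- if (mode == "eigen") {
    sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  } else {
    sort(diag(S))
  }
  lam <- pmax(lam, 0)
  structure(list(lambda_sq = lam, rg_sq = sum(lam), mode = mode),
            class = "gyration")
}

#' Shape parameters of every aggregate in a trajectory, binned by size
#'
#' For each frame and each aggregate, unwraps the member beads and
#' computes the gyration size parameters of the insoluble core (B beads)
#' and of the whole aggregate (A + B), then averages within each
#' association number.
#'
#' @param trajectory A `dpd_trajectory` or list of `dpd_config` frames.
#' @param aggregates Output of [aggregate_trajectory()]; recomputed if
#'   missing.
#' @param subset Which bead subsets to analyse (default both core and
#'   whole).
#' @param mode Passed to [gyration()].
#' @param min_a_s Skip aggregates smaller than this (default 1).
#' @param ... Passed to [aggregate_trajectory()] when recomputing.
#' @return A tibble of class `shape_summary`: `a_s`, `subset`,
#'   `lambda1_sq`, `lambda2_sq`, `lambda3_sq`, `rg_sq`, `n_obs`.
#' @export
shape_vs_size <- function(trajectory, aggregates = NULL,
                          subset = c("core", "whole"),
                          mode = c("eigen", "diagonal"), min_a_s = 1, ...) {
  mode <- match.arg(mode)
  subset <- match.arg(subset, several.ok = TRUE)
  frames <- if (inherits(trajectory, "dpd_trajectory")) trajectory$frames
            else trajectory
  if (is.null(aggregates)) aggregates <- aggregate_trajectory(frames, ...)
  spec_sets <- list(core = "B", whole = c("A", "B"))
  n_ambiguous <- 0L
  rows <- purrr::pmap_dfr(
    aggregates[c("frame", "a_s", "chains")],
    function(frame, a_s, chains) {
      if (a_s < min_a_s) return(NULL)
      cfg <- frames[[frame]]
      # per-aggregate ambiguity warnings are tallied and reported once
      pos <- withCallingHandlers(
        unwrap_aggregate(cfg, chains, species = c("A", "B")),
        warning = function(w) {
          if (grepl("ambiguous", conditionMessage(w))) {
            n_ambiguous <<- n_ambiguous + 1L
            invokeRestart("muffleWarning")
          }
        }
      )
      sp <- attr(pos, "species")
      purrr::map_dfr(subset, function(ss) {
        keep <- sp %in% spec_sets[[ss]]
        if (!any(keep)) return(NULL)
        lam <- gyration(pos[keep, , drop = FALSE], mode = mode)$lambda_sq
        tibble::tibble(a_s = a_s, subset = ss, lambda1_sq = lam[1],
                       lambda2_sq = lam[2], lambda3_sq = lam[3])
      })
    }
  )
  if (n_ambiguous > 0L) {
    rlang::warn(sprintf(
      "%d aggregate observation%s spanned more than half the box; their unwraps are ambiguous",
      n_ambiguous, if (n_ambiguous == 1L) "" else "s"))
  }
  out <- rows |>
    dplyr::group_by(.data$a_s, .data$subset) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("lambda"), mean),
                     n_obs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(rg_sq = .data$lambda1_sq + .data$lambda2_sq +
                    .data$lambda3_sq, .before = "n_obs")
  class(out) <- c("shape_summary", class(out))
  out
}

#' Size-scaling exponent of the gyration parameters
#'
#' Fits `lambda_i` proportional to `A_S^a` by least squares on the
#' log-log scale over a stated window of association numbers.  Compact
#' space-filling aggregates give `a = 1/3` (the mass of a homogeneous
#' sphere grows with the cube of its radius); rods approach `a = 1` in
#' the long component.
#'
#' @param shape A `shape_summary` tibble from [shape_vs_size()], or any
#'   tibble with columns `a_s` and `lambda*_sq`.
#' @param subset Which subset rows to use when present (default
#'   `"core"`).
#' @param window Optional length-2 A_S range to fit over (default: all
#'   rows present).
#' @return Tibble with `component` (`lambda1`, `lambda2`, `lambda3`,
#'   `rg`), `exponent` and `n_points`.
#' @export
fit_size_exponent <- function(shape, subset = "core", window = NULL) {
  d <- shape
  if ("subset" %in% names(d)) d <- d[d$subset == subset, ]
  if (!is.null(window)) d <- d[d$a_s >= window[1] & d$a_s <= window[2], ]
  if (nrow(d) < 2) rlang::abort("need at least two association numbers to fit")
  comps <- c(lambda1 = "lambda1_sq", lambda2 = "lambda2_sq",
             lambda3 = "lambda3_sq", rg = "rg_sq")
  comps <- comps[comps %in% names(d)]
  purrr::imap_dfr(comps, function(col, nm) {
    y <- d[[col]]
    ok <- y > 0 & d$a_s > 0
    # lambda ~ A_S^a  =>  log lambda = const + a log A_S; lambda = sqrt(col)
    fit <- stats::lm(log(sqrt(y[ok])) ~ log(d$a_s[ok]))
    tibble::tibble(component = nm, exponent = unname(stats::coef(fit)[2]),
                   n_points = sum(ok))
  })
}

#' Asphericity of a gyration result
#'
#' `b = lambda3^2 - (lambda1^2 + lambda2^2) / 2`: zero for a perfect
#' sphere, growing with elongation; the quantitative core of
#' sphere-versus-rod discrimination.
#'
#' @param g A `gyration` object or a numeric length-3 vector of ordered
#'   `lambda^2`.
#' @return Scalar asphericity (length^2).
#' @export
asphericity <- function(g) {
  lam <- if (inherits(g, "gyration")) g$lambda_sq else sort(g)
  lam[3] - (lam[1] + lam[2]) / 2
}
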
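# Aggregate detection via the contact-pair criterion and the
# adsorbed/free classification of aggregates in slits.

#' Count core-bead contact pairs between chains
#'
#' Two insoluble (B) beads on different chains form a contact pair when
#' their distance is below the interaction cutoff; distances use the
#' minimum image in periodic directions only.  The pair counts are the
#' raw material of the aggregate criterion of [cluster_aggregates()].
#'
#' @param config A `dpd_config`.
#' @param rc Contact cutoff (default 1 r_c, the interaction cutoff).
#' @return Tibble with `chain_i`, `chain_j` (`chain_i < chain_j`) and
#'   `n_contacts`, one row per chain pair with at least one contact.
#' @export
contact_pairs <- function(config, rc = 1) {
  stopifnot(inherits(config, "dpd_config"))
  box <- config_box(config)
  sel <- config$species == "B" & config$chain_id >= 0L
  if (!any(sel)) {
    return(tibble::tibble(chain_i = integer(), chain_j = integer(),
                          n_contacts = integer()))
  }
  L <- c(if (box$kind == "bulk") box$Lx else box$D, box$Ly, box$Lz)
  m <- cpp_contact_pairs(
    pos = cbind(config$x[sel], config$y[sel], config$z[sel]),
    chain = config$chain_id[sel],
    boxlen = L, periodic = unname(box$periodic), rc = rc
  )
  tibble::tibble(chain_i = m[, 1], chain_j = m[, 2], n_contacts = m[, 3])
}

#' Partition chains into aggregates
#'
#' Two chains belong to the same aggregate when they share at least
#' `threshold` B-B contact pairs (default 3, the criterion that best
#' matches visual classification of snapshots; values 1-4 are
#' meaningful).  Aggregates are the connected components of the
#' resulting chain graph, so membership is transitive; chains connected
#' to nothing are unimers (aggregates of size 1).
#'
#' @param config A `dpd_config`, or a contact tibble from
#'   [contact_pairs()] (then `chains` must list all chain ids).
#' @param threshold Minimum contact-pair count for an edge (>= 1).
#' @param rc Contact cutoff passed to [contact_pairs()].
#' @param chains Integer vector of all chain ids; inferred from a
#'   `dpd_config` automatically.
#' @return An `aggregate_set` tibble: one row per aggregate with
#'   `aggregate` (id), `a_s` (association number) and `chains`
#'   (list-column of member chain ids).  The per-chain membership vector
#'   is attached as attribute `membership`.
#' @export
cluster_aggregates <- function(config, threshold = 3, rc = 1, chains = NULL) {
  if (threshold < 1) rlang::abort("contact threshold must be at least 1")
  if (inherits(config, "dpd_config")) {
    contacts <- contact_pairs(config, rc)
    chains <- sort(unique(config$chain_id[config$chain_id >= 0L]))
  } else {
    contacts <- config
    if (is.null(chains)) {
      chains <- sort(unique(c(contacts$chain_i, contacts$chain_j)))
    }
  }
  n <- length(chains)
  if (n == 0) {
    out <- tibble::tibble(aggregate = integer(), a_s = integer(),
                          chains = list())
    attr(out, "membership") <- integer()
    class(out) <- c("aggregate_set", class(out))
    return(out)
  }
  keep <- contacts$n_contacts >= threshold
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = match(contacts$chain_i[keep], chains),
                   to = match(contacts$chain_j[keep], chains)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  comp <- igraph::components(g)$membership
  member <- split(chains, comp)
  out <- tibble::tibble(
    aggregate = seq_along(member),
    a_s = unname(lengths(member)),
    chains = unname(member)
  )
  mem <- stats::setNames(rep(out$aggregate, out$a_s), unlist(member))
  attr(out, "membership") <- mem[order(as.integer(names(mem)))]
  class(out) <- c("aggregate_set", class(out))
  out
}

#' Chains with enough core beads touching a wall
#'
#' A chain is wall-contacting when at least `bead_threshold` of its B
#' beads lie within `wall_cutoff` of the nearest reflecting plane
#' (mirroring the bead-bead contact rule, and independent of the random
#' placement of the frozen wall beads).
#'
#' @param config A slit `dpd_config`.
#' @param wall_cutoff Wall-contact distance (default 1 r_c).
#' @param bead_threshold Minimum number of contacting B beads (default 3).
#' @return Integer vector of wall-contacting chain ids.
#' @export
wall_contact_chains <- function(config, wall_cutoff = 1, bead_threshold = 3) {
  box <- config_box(config)
  if (box$kind != "slit") {
    rlang::abort("wall contact is only defined for slit configurations")
  }
  half <- box$D / 2
  sel <- config$species == "B" & config$chain_id >= 0L
  d <- half - abs(config$x[sel])
  cnt <- table(config$chain_id[sel][d < wall_cutoff])
  as.integer(names(cnt)[cnt >= bead_threshold])
}

#' Label aggregates as adsorbed or free
#'
#' An aggregate (or a unimer) is adsorbed when it contains at least one
#' chain with three or more B beads in contact with a wall; everything
#' else is free (non-adsorbed, inside the slit).
#'
#' @param config The slit `dpd_config` the aggregates came from.
#' @param aggregates An `aggregate_set` from [cluster_aggregates()];
#'   computed from `config` if missing.
#' @param wall_cutoff Wall-contact distance (default 1 r_c).
#' @param bead_threshold Minimum contacting B beads per chain (default 3).
#' @param ... Passed to [cluster_aggregates()] when `aggregates` is
#'   missing.
#' @return The `aggregate_set` with an added `label` column
#'   (`"adsorbed"` / `"free"`).
#' @export
classify_adsorption <- function(config, aggregates = NULL, wall_cutoff = 1,
                                bead_threshold = 3, ...) {
  box <- config_box(config)
  if (box$kind != "slit") {
    rlang::abort("adsorption classification requires a slit configuration")
  }
  if (is.null(aggregates)) aggregates <- cluster_aggregates(config, ...)
  touching <- wall_contact_chains(config, wall_cutoff, bead_threshold)
  aggregates$label <- ifelse(
    purrr::map_lgl(aggregates$chains, ~ any(.x %in% touching)),
    "adsorbed", "free"
  )
  aggregates
}

#' Aggregate analysis of a whole trajectory
#'
#' Runs [cluster_aggregates()] (and, for slit trajectories,
#' [classify_adsorption()]) on every stored frame independently; no
#' temporal identity is tracked because frames are sampled to be
#' statistically independent.
#'
#' @param trajectory A `dpd_trajectory` or list of `dpd_config` frames.
#' @param threshold Contact-pair threshold (default 3).
#' @param rc Contact cutoff.
#' @param classify Label adsorption (default: TRUE for slit frames).
#' @param wall_cutoff Wall-contact distance for the classification.
#' @return Tibble with one row per aggregate per frame: `frame`,
#'   `aggregate`, `a_s`, `chains` (list-column) and, when classified,
#'   `label`.
#' @export
aggregate_trajectory <- function(trajectory, threshold = 3, rc = 1,
                                 classify = NULL, wall_cutoff = 1) {
  frames <- if (inherits(trajectory, "dpd_trajectory")) trajectory$frames
            else trajectory
  if (!length(frames)) rlang::abort("trajectory has no frames")
  if (is.null(classify)) {
    classify <- config_box(frames[[1]])$kind == "slit"
  }
  purrr::imap_dfr(frames, function(cfg, i) {
    aggs <- cluster_aggregates(cfg, threshold = threshold, rc = rc)
    if (classify) {
      aggs <- classify_adsorption(cfg, aggs, wall_cutoff = wall_cutoff)
    }
    dplyr::mutate(tibble::as_tibble(aggs), frame = i, .before = 1)
  })
}
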
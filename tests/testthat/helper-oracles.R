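# Shared fixtures and independent oracles for the suite.

# hand-built configuration from a bead table (defaults filled in)
make_config <- function(df, box, chain = chain_spec()) {
  for (col in c("vx", "vy", "vz")) if (is.null(df[[col]])) df[[col]] <- 0
  if (is.null(df$frozen)) df$frozen <- FALSE
  if (is.null(df$chain_id)) df$chain_id <- -1L
  dpd_config(df, box, chain)
}

# a straight A5B5 chain along +z starting at `origin`, bond length `b`
straight_chain <- function(origin, chain_id, b = 0.4, chain = chain_spec()) {
  n <- chain$n
  tibble::tibble(
    species = chain$species,
    x = origin[1], y = origin[2], z = origin[3] + b * (seq_len(n) - 1),
    vx = 0, vy = 0, vz = 0, chain_id = as.integer(chain_id), frozen = FALSE
  )
}

# brute-force transitive closure clustering over a contact table:
# boolean adjacency, squared to fixed point, then component extraction
oracle_cluster <- function(contacts, chains, threshold = 3) {
  n <- length(chains)
  adj <- diag(TRUE, n)
  for (k in seq_len(nrow(contacts))) {
    if (contacts$n_contacts[k] >= threshold) {
      i <- match(contacts$chain_i[k], chains)
      j <- match(contacts$chain_j[k], chains)
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[which(adj[i, ])] <- cid
    }
  }
  unname(lapply(split(chains, comp), sort))
}

# closed-form eigenvalues of a symmetric 3x3 matrix (trigonometric form),
# independent of base::eigen
oracle_eigen_sym3 <- function(S) {
  p1 <- S[1, 2]^2 + S[1, 3]^2 + S[2, 3]^2
  q <- sum(diag(S)) / 3
  p2 <- sum((diag(S) - q)^2) + 2 * p1
  if (p2 < 1e-30) return(rep(q, 3))
  p <- sqrt(p2 / 6)
  B <- (S - q * diag(3)) / p
  r <- det(B) / 2
  r <- min(max(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  sort(c(e1, e3, 3 * q - e1 - e3))
}

# all-pairs minimum-image B-B contact counting in plain R
oracle_contacts <- function(config, rc = 1) {
  box <- config_box(config)
  sel <- which(config$species == "B" & config$chain_id >= 0)
  L <- c(if (box$kind == "bulk") box$Lx else box$D, box$Ly, box$Lz)
  per <- box$periodic
  res <- list()
  for (ii in seq_along(sel)) {
    for (jj in seq_along(sel)) {
      if (jj <= ii) next
      i <- sel[ii]; j <- sel[jj]
      if (config$chain_id[i] == config$chain_id[j]) next
      d <- c(config$x[i] - config$x[j], config$y[i] - config$y[j],
             config$z[i] - config$z[j])
      for (k in 1:3) if (per[k]) d[k] <- d[k] - L[k] * round(d[k] / L[k])
      if (sum(d^2) < rc^2) {
        key <- paste(sort(c(config$chain_id[i], config$chain_id[j])),
                     collapse = "-")
        res[[key]] <- (res[[key]] %||% 0L) + 1L
      }
    }
  }
  if (!length(res)) {
    return(tibble::tibble(chain_i = integer(), chain_j = integer(),
                          n_contacts = integer()))
  }
  ids <- do.call(rbind, strsplit(names(res), "-"))
  tibble::tibble(chain_i = as.integer(ids[, 1]), chain_j = as.integer(ids[, 2]),
                 n_contacts = unlist(res, use.names = FALSE)) |>
    dplyr::arrange(chain_i, chain_j)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniformly random rotation matrix
random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# lattice-filled ball of points with spacing h: a rigid "homogeneous
# sphere" whose point count stands in for the association number
lattice_sphere <- function(radius, h = 0.5) {
  g <- seq(-radius, radius, by = h)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
}
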
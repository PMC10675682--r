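# Plain-text serialization: extended-XYZ trajectories, planted-truth
# sidecars, and structured run-configuration files.  Text is the format
# of record: inspectable, diffable, and round-trips bit-exactly (17
# significant digits).

fmt_num <- function(x) sprintf("%.17g", x)

config_header <- function(config, extra = character()) {
  box <- config_box(config)
  kv <- c(
    step = attr(config, "time") %||% 0L,
    kind = box$kind,
    Lx = fmt_num(box$Lx), Ly = fmt_num(box$Ly), Lz = fmt_num(box$Lz)
  )
  if (box$kind == "slit") {
    kv <- c(kv, D = fmt_num(box$D), x_c = fmt_num(box$x_c),
            a_wall = fmt_num(box$a_wall))
  }
  kv <- c(kv, extra)
  paste(paste0(names(kv), "=", kv), collapse = " ")
}

#' Append a configuration as one extended-XYZ frame
#'
#' The dialect: a bead-count line; a key=value comment line carrying the
#' step index and box geometry; then one line per bead with columns
#' `species x y z vx vy vz chain_id frozen`.  Numbers carry 17
#' significant digits so `read_xyz(write_xyz(...))` reproduces every
#' field bit-exactly.
#'
#' @param config A `dpd_config`.
#' @param path File path; the frame is appended when `append = TRUE`.
#' @param append Append to an existing trajectory (default FALSE).
#' @param extra Named character vector of additional header key=value
#'   pairs (e.g. `c(kT = "1.002")`).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(config, path, append = FALSE, extra = character()) {
  stopifnot(inherits(config, "dpd_config"))
  lines <- c(
    as.character(nrow(config)),
    config_header(config, extra),
    sprintf("%s %s %s %s %s %s %s %d %d",
            config$species,
            fmt_num(config$x), fmt_num(config$y), fmt_num(config$z),
            fmt_num(config$vx), fmt_num(config$vy), fmt_num(config$vz),
            config$chain_id, as.integer(config$frozen))
  )
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a whole trajectory in extended-XYZ
#'
#' @param trajectory A `dpd_trajectory` or list of `dpd_config` frames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(trajectory, path) {
  frames <- traj_frames(trajectory)
  kT <- if (inherits(trajectory, "dpd_trajectory")) {
    stats::setNames(trajectory$log$kT, trajectory$log$step)
  } else NULL
  first <- TRUE
  for (cfg in frames) {
    extra <- character()
    if (!is.null(kT)) {
      k <- kT[as.character(attr(cfg, "time"))]
      if (!is.na(k)) extra <- c(kT = fmt_num(unname(k)))
    }
    write_xyz(cfg, path, append = !first, extra = extra)
    first <- FALSE
  }
  invisible(path)
}

parse_header <- function(line, lineno) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  kv <- strsplit(toks, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    rlang::abort(sprintf("malformed header at line %d: '%s'", lineno, line))
  }
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

header_box <- function(h, lineno) {
  need <- c("kind", "Lx", "Ly", "Lz")
  if (!all(need %in% names(h))) {
    rlang::abort(sprintf("header at line %d lacks box geometry", lineno))
  }
  if (h[["kind"]] == "slit") {
    slit_box(D = as.numeric(h[["D"]] %||% h[["Lx"]]),
             Ly = as.numeric(h[["Ly"]]), Lz = as.numeric(h[["Lz"]]),
             x_c = as.numeric(h[["x_c"]] %||% "1.2"),
             a_wall = as.numeric(h[["a_wall"]] %||% "25"))
  } else {
    box <- bulk_box(as.numeric(h[["Lx"]]))
    box$Ly <- as.numeric(h[["Ly"]]); box$Lz <- as.numeric(h[["Lz"]])
    box
  }
}

#' Read an extended-XYZ trajectory
#'
#' Parses every frame written by [write_xyz()] /
#' [write_xyz_trajectory()].  Malformed content raises an error naming
#' the offending line; files in a foreign extended-XYZ layout (missing
#' the `chain_id` / `frozen` columns) are rejected explicitly.
#'
#' @param path Input file.
#' @param partial If TRUE, a truncated final frame is dropped with a
#'   warning instead of raising an error, and the complete frames are
#'   returned.
#' @return List of `dpd_config` frames.
#' @export
read_xyz <- function(path, partial = FALSE) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0) {
      rlang::abort(sprintf("expected a bead count at line %d", i))
    }
    if (i + 1L + n > length(lines)) {
      msg <- sprintf("truncated frame starting at line %d", i)
      if (partial) { rlang::warn(msg); break }
      rlang::abort(msg)
    }
    h <- parse_header(lines[i + 1L], i + 1L)
    box <- header_box(h, i + 1L)
    body <- if (n > 0) lines[(i + 2L):(i + n + 1L)] else character()
    if (n == 0) {
      beads <- tibble::tibble(species = character(), x = numeric(),
                              y = numeric(), z = numeric(), vx = numeric(),
                              vy = numeric(), vz = numeric(),
                              chain_id = integer(), frozen = logical())
    } else {
      toks <- strsplit(trimws(body), "\\s+")
      nf <- lengths(toks)
      if (any(nf < 9)) {
        bad <- i + 1L + which(nf < 9)[1]
        rlang::abort(sprintf(
          "unsupported extended-XYZ dialect: line %d has %d columns, need 9 (species x y z vx vy vz chain_id frozen)",
          bad, nf[which(nf < 9)[1]]))
      }
      m <- do.call(rbind, toks)
      sp <- m[, 1]
      if (!all(sp %in% DPD_SPECIES)) {
        bad <- i + 1L + which(!(sp %in% DPD_SPECIES))[1]
        rlang::abort(sprintf("unknown species at line %d", bad))
      }
      num <- apply(m[, 2:9, drop = FALSE], 2, as.numeric)
      if (n == 1) num <- matrix(num, nrow = 1)
      if (any(!is.finite(num[, 1:6]))) {
        rlang::abort(sprintf("non-numeric coordinate in frame starting at line %d", i))
      }
      beads <- tibble::tibble(species = sp, x = num[, 1], y = num[, 2],
                              z = num[, 3], vx = num[, 4], vy = num[, 5],
                              vz = num[, 6],
                              chain_id = as.integer(num[, 7]),
                              frozen = num[, 8] != 0)
    }
    frames[[length(frames) + 1L]] <-
      dpd_config(beads, box, time = as.integer(h[["step"]] %||% "0"))
    i <- i + 2L + n
  }
  frames
}

#' Serialize planted ground truth as a sidecar table
#'
#' @param config A planted `dpd_config` (from [planted_config()]).
#' @param path Output path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(config, path) {
  tr <- planted_truth(config)
  df <- data.frame(
    object = tr$object, shape = tr$shape, a_s = tr$a_s,
    chains = vapply(tr$chains, paste, "", collapse = ","),
    label = ifelse(is.na(tr$label), "NA", tr$label)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a planted-truth sidecar
#'
#' @param path Sidecar file from [write_planted_truth()].
#' @return Truth tibble (same shape as [planted_truth()]).
#' @export
read_planted_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  tibble::tibble(
    object = as.integer(df$object), shape = df$shape,
    a_s = as.integer(df$a_s),
    chains = lapply(strsplit(df$chains, ","), as.integer),
    label = ifelse(df$label == "NA", NA_character_, df$label)
  )
}

#' Write a run configuration file
#'
#' Key/value text with `[species]`, `[interactions]`, `[geometry]` and
#' `[run]` sections; every model default is expressible and overridable.
#' The same structure that [scenario()] produces in memory.
#'
#' @param scn A scenario-style list (see [scenario()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(scn, path) {
  it <- scn$interactions
  pairs <- t(utils::combn(DPD_SPECIES, 2))
  pair_lines <- sprintf("a_%s%s = %s", pairs[, 1], pairs[, 2],
                        fmt_num(it$a[cbind(pairs[, 1], pairs[, 2])]))
  diag_lines <- sprintf("a_%s%s = %s", DPD_SPECIES, DPD_SPECIES,
                        fmt_num(diag(it$a)))
  geom <- if (scn$box$kind == "slit") {
    c(sprintf("kind = slit"), sprintf("D = %s", fmt_num(scn$box$D)),
      sprintf("Ly = %s", fmt_num(scn$box$Ly)),
      sprintf("Lz = %s", fmt_num(scn$box$Lz)),
      sprintf("x_c = %s", fmt_num(scn$box$x_c)),
      sprintf("a_wall = %s", fmt_num(scn$box$a_wall)))
  } else {
    c("kind = bulk", sprintf("L = %s", fmt_num(scn$box$Lx)))
  }
  lines <- c(
    sprintf("# run configuration: %s", scn$name %||% "custom"),
    "[species]",
    sprintf("blocks = %s", paste0(names(scn$chain$blocks), scn$chain$blocks,
                                  collapse = " ")),
    sprintf("K = %s", fmt_num(scn$chain$K)),
    sprintf("r0 = %s", fmt_num(scn$chain$r0)),
    "",
    "[interactions]",
    sprintf("gamma = %s", fmt_num(it$gamma)),
    sprintf("sigma = %s", fmt_num(it$sigma)),
    diag_lines, pair_lines,
    "",
    "[geometry]", geom,
    "",
    "[run]",
    sprintf("rho = %s", fmt_num(scn$rho)),
    sprintf("n_chains = %d", scn$n_chains),
    sprintf("pre_equil_steps = %d", as.integer(scn$pre_equil_steps)),
    sprintf("steps = %d", as.integer(scn$steps)),
    sprintf("sample_period = %d", as.integer(scn$sample_period))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration file
#'
#' @param path File written by [write_run_config()] (or by hand in the
#'   same format).
#' @return A scenario-style list usable with [run_scenario()].
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  kv <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      next
    }
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) rlang::abort(sprintf("malformed line: '%s'", ln))
    kv[[paste0(section, ".", trimws(parts[1]))]] <- trimws(parts[2])
  }
  get <- function(key, default = NULL) kv[[key]] %||% default
  # species
  blocks_str <- get("species.blocks", "A5 B5")
  toks <- strsplit(blocks_str, "\\s+")[[1]]
  blocks <- stats::setNames(
    as.integer(sub("^[A-Z]", "", toks)),
    substr(toks, 1, 1)
  )
  chain <- chain_spec(blocks, K = as.numeric(get("species.K", "4")),
                      r0 = as.numeric(get("species.r0", "0")))
  # interactions
  overrides <- list()
  for (key in names(kv)) {
    if (grepl("^interactions\\.a_", key)) {
      overrides[[sub("^interactions\\.a_", "", key)]] <- as.numeric(kv[[key]])
    }
  }
  gam <- as.numeric(get("interactions.gamma", "4.5"))
  it <- interaction_table(a = overrides, gamma = gam,
                          sigma = as.numeric(get("interactions.sigma",
                                                 fmt_num(sqrt(2 * gam)))))
  # geometry
  box <- if (identical(get("geometry.kind"), "slit")) {
    slit_box(D = as.numeric(get("geometry.D")),
             Ly = as.numeric(get("geometry.Ly", "25")),
             Lz = as.numeric(get("geometry.Lz", "25")),
             x_c = as.numeric(get("geometry.x_c", "1.2")),
             a_wall = as.numeric(get("geometry.a_wall", "25")))
  } else {
    bulk_box(as.numeric(get("geometry.L", "25")))
  }
  n_chains <- as.integer(get("run.n_chains", "0"))
  list(name = "from-file", box = box, interactions = it, chain = chain,
       rho = as.numeric(get("run.rho", "3")), n_chains = n_chains,
       c_percent = concentration(n_chains, chain$n,
                                 as.numeric(get("run.rho", "3")),
                                 box_volume(box)),
       pre_equil_steps = as.integer(get("run.pre_equil_steps", "0")),
       steps = as.integer(get("run.steps", "1000")),
       sample_period = as.integer(get("run.sample_period", "100")))
}
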
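#' Write a density-of-states table
#'
#' Tab-separated table with `#`-prefixed header comments carrying the run
#' metadata (params, schedule, steps, seed), then columns `energy` (exact
#' integer), `ln_g` (15 significant digits) and `visits`.
#'
#' @param dos A [dos_estimate()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dos <- function(dos, path) {
  meta <- attr(dos, "meta")
  hdr <- c("# samcpoly density-of-states table")
  if (!is.null(meta$params))
    hdr <- c(hdr, sprintf("# params: n=%d L=%.15g lambda=%.15g eps=%.15g",
                          meta$params$n, meta$params$bond_length,
                          meta$params$well_width, meta$params$well_depth))
  if (!is.null(meta$schedule))
    hdr <- c(hdr, sprintf("# schedule: gamma0=%.15g t0=%.15g",
                          meta$schedule$gamma0, meta$schedule$t0))
  if (!is.null(meta$n_steps)) hdr <- c(hdr, sprintf("# steps: %.15g", meta$n_steps))
  if (!is.null(meta$seed)) hdr <- c(hdr, sprintf("# seed: %d", meta$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("energy\tln_g\tvisits", con)
  writeLines(sprintf("%d\t%.15g\t%d", as.integer(dos$energy), dos$ln_g,
                     as.integer(round(dos$visits))), con)
  invisible(path)
}

parse_kv <- function(s) {
  # "a=1 b=2" -> named list of numerics
  parts <- strsplit(trimws(s), "\\s+")[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) as.numeric(p[2])),
                  vapply(kv, `[`, "", 1))
}

#' Read a density-of-states table
#'
#' Inverse of [write_dos()]: losslessly restores energies (exact integers),
#' `ln_g` and visit counts, and parses the header metadata back into a
#' [model_params()] / [samc_schedule()] when present.  Malformed rows,
#' duplicate energies and a missing column header are errors naming the
#' offending line; a legacy file without the `visits` column loads with
#' visits = 0 and a warning.
#'
#' @param path File written by [write_dos()].
#' @return A [dos_estimate()].
#' @export
read_dos <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty DOS file: ", path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  if (!length(body)) stop("no column header line in ", path)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!all(c("energy", "ln_g") %in% cols))
    stop("line ", which(!is_hdr)[1], ": column header must contain ",
         "'energy' and 'ln_g', got: ", body[1])
  has_visits <- "visits" %in% cols
  if (!has_visits)
    warning("legacy DOS file without 'visits' column; visits set to 0")
  rows <- body[-1]
  rows <- rows[nzchar(trimws(rows))]
  fields <- strsplit(rows, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(cols))
  if (length(bad))
    stop("line ", which(!is_hdr)[1 + bad[1]], ": expected ", length(cols),
         " tab-separated fields")
  tab <- do.call(rbind, fields)
  e <- as.numeric(tab[, match("energy", cols)])
  if (anyNA(e) || any(e != round(e)))
    stop("non-integer energy value in ", path)
  if (anyDuplicated(e))
    stop("duplicate energy row for E = ", e[duplicated(e)][1], " in ", path)
  lng <- as.numeric(tab[, match("ln_g", cols)])
  vis <- if (has_visits) as.numeric(tab[, match("visits", cols)]) else
    numeric(length(e))
  o <- order(e)
  meta <- list()
  for (h in hdr) {
    if (grepl("^# params:", h)) {
      kv <- parse_kv(sub("^# params:", "", h))
      meta$params <- model_params(kv$n, kv$L, kv$lambda, kv$eps)
    } else if (grepl("^# schedule:", h)) {
      kv <- parse_kv(sub("^# schedule:", "", h))
      meta$schedule <- samc_schedule(kv$gamma0, kv$t0)
    } else if (grepl("^# steps:", h)) {
      meta$n_steps <- as.numeric(sub("^# steps:", "", h))
    } else if (grepl("^# seed:", h)) {
      meta$seed <- as.integer(sub("^# seed:", "", h))
    }
  }
  dos_estimate(e[o], lng[o], vis[o], meta = meta)
}

#' Write a conformation as an XYZ file
#'
#' Standard XYZ: first line the atom count, second line a comment carrying
#' `N=<n> L=<l> lambda=<lambda> E=<e>`, then one `C x y z` line per monomer
#' with 15 significant digits.
#'
#' @param conf N x 3 coordinate matrix.
#' @param path Output path.
#' @param params Optional [model_params()] for the metadata comment (also
#'   used to recompute E).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(conf, path, params = NULL) {
  conf <- as_coord_matrix(conf)
  n <- nrow(conf)
  comment <- if (!is.null(params)) {
    e <- total_energy(conf, params)
    sprintf("N=%d L=%.15g lambda=%.15g E=%g", params$n, params$bond_length,
            params$well_width, e)
  } else sprintf("N=%d", n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(n), comment), con)
  writeLines(sprintf("C %.15g %.15g %.15g", conf[, 1], conf[, 2], conf[, 3]),
             con)
  invisible(path)
}

#' Read an XYZ conformation file
#'
#' @param path File written by [write_xyz()] (or any standard XYZ).
#' @return N x 3 coordinate matrix; when the comment line carries
#'   `N= L= lambda=` metadata, the matching [model_params()] is attached as
#'   attribute `"params"`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed XYZ file (need count, comment, atoms)")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("first XYZ line must be the atom count")
  if (length(lines) < 2 + n)
    stop("atom-count mismatch: header says ", n, " atoms, file has ",
         length(lines) - 2)
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  if (any(lengths(rows) < 4)) stop("malformed atom line in ", path)
  conf <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  if (anyNA(conf)) stop("non-numeric coordinate in ", path)
  if (grepl("L=", lines[2], fixed = TRUE)) {
    kv <- parse_kv(lines[2])
    if (!is.null(kv$N) && !is.null(kv$L) && !is.null(kv$lambda))
      attr(conf, "params") <- model_params(kv$N, kv$L, kv$lambda)
  }
  conf
}

#' Write / read a run configuration
#'
#' The full run configuration (model params, schedule, move set, steps,
#' seed, grid policy, observable collection, output paths) round-trips
#' losslessly through a YAML document.
#'
#' @param config Named list as assembled by [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly ([write_run_config()]); the config list
#'   ([read_run_config()]).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  yaml::read_yaml(path)
}

#' Assemble a run configuration
#'
#' @param n,bond_length,well_width Model parameters.
#' @param steps,gamma0,t0,seed Run controls.
#' @param grid_policy,obs,obs_stride Engine options as in [run_samc()].
#' @param move_weights,max_angles Move-set options as in [move_set()].
#' @param out Output path for the DOS table.
#' @return Named list suitable for [write_run_config()].
#' @export
run_config <- function(n, bond_length, well_width = 1.1, steps = 1e6,
                       gamma0 = 1.0, t0 = 1e6, seed = 1L,
                       grid_policy = "adaptive", obs = "final_half",
                       obs_stride = 1L,
                       move_weights = c(1, 1, 1), max_angles = c(pi, pi, pi),
                       out = "dos.tsv") {
  list(n = as.integer(n), bond_length = bond_length, well_width = well_width,
       steps = steps, gamma0 = gamma0, t0 = t0, seed = as.integer(seed),
       grid_policy = grid_policy, obs = obs, obs_stride = as.integer(obs_stride),
       move_weights = as.numeric(move_weights),
       max_angles = as.numeric(max_angles), out = out)
}

#' Write per-energy observables
#'
#' TSV (energy, count, rg2_mean); contact-frequency matrices go to one dense
#' TSV per energy level next to `path` (suffix `_contacts_E<e>.tsv`) when
#' `contacts = TRUE`.
#'
#' @param obs An `energy_observables` table.
#' @param path Output TSV path.
#' @param contacts Also write the per-energy contact matrices.
#' @return `path`, invisibly.
#' @export
write_observables <- function(obs, path, contacts = FALSE) {
  utils::write.table(as.data.frame(obs)[, c("energy", "count", "rg2_mean")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (contacts) {
    cf <- attr(obs, "contact_freq")
    base <- sub("\\.tsv$", "", path)
    for (e in names(cf)) {
      if (is.null(cf[[e]])) next
      utils::write.table(cf[[e]], sprintf("%s_contacts_E%s.tsv", base, e),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read per-energy observables
#'
#' @param path TSV written by [write_observables()].
#' @return An `energy_observables` data frame (without contact matrices).
#' @export
read_observables <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  class(out) <- c("energy_observables", "data.frame")
  out
}
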
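#' Construct a duplex count table
#'
#' The central observable of the pipeline: per-sample, per-site counts of
#' total duplex molecules (`t`) and mutant duplex molecules (`n`) at each
#' fingerprint site. One row per (sample, site) pair.
#'
#' @param sample_id,site_id character vectors.
#' @param t non-negative integer total duplex molecules.
#' @param n non-negative integer mutant duplex molecules, `0 <= n <= t`.
#' @param panel optional [panel_fingerprint()] to bind; when given, all
#'   `site_id` values must belong to the panel.
#' @return An object of class `duplex_count_table` (a data.frame).
#' @export
duplex_count_table <- function(sample_id, site_id, t, n, panel = NULL) {
  tab <- data.frame(
    sample_id = as.character(sample_id),
    site_id = as.character(site_id),
    t = as.integer(round(t)),
    n = as.integer(round(n)),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("duplex_count_table", "data.frame")
  validate_counts(tab, panel)
}

#' Validate a duplex count table
#'
#' Invariants: `0 <= n <= t` on every row, each (sample_id, site_id) pair
#' occurs at most once, and (when a panel is supplied) every site_id belongs
#' to the panel. An empty table (zero rows) is valid.
#'
#' @param tab a `duplex_count_table`.
#' @param panel optional bound `panel_fingerprint`.
#' @return The table if valid, else an error.
#' @export
validate_counts <- function(tab, panel = NULL) {
  need <- c("sample_id", "site_id", "t", "n")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("count table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) return(tab)
  if (anyNA(tab$t) || anyNA(tab$n)) {
    stop("count table contains missing t or n values", call. = FALSE)
  }
  if (any(tab$t < 0L) || any(tab$n < 0L)) {
    stop("duplex counts must be non-negative", call. = FALSE)
  }
  bad <- tab$n > tab$t
  if (any(bad)) {
    stop(sprintf("mutant count exceeds total count on %d row(s), e.g. sample %s site %s (n=%d > t=%d)",
                 sum(bad), tab$sample_id[bad][1L], tab$site_id[bad][1L],
                 tab$n[bad][1L], tab$t[bad][1L]), call. = FALSE)
  }
  key <- paste(tab$sample_id, tab$site_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicated (sample_id, site_id) pair: ",
         gsub("\r", " / ", d, fixed = TRUE), call. = FALSE)
  }
  if (!is.null(panel)) {
    unknown <- setdiff(unique(tab$site_id), panel$site_id)
    if (length(unknown)) {
      stop("site_id not in panel: ",
           paste(utils::head(unknown, 10L), collapse = ", "),
           if (length(unknown) > 10L) sprintf(" ... (%d total)", length(unknown)),
           call. = FALSE)
    }
  }
  tab
}

#' Read a duplex count table from TSV
#'
#' Expects a header line `sample_id  site_id  t  n`. A file containing only
#' the header yields a valid empty table. When a panel is supplied, rows are
#' validated against it; sites present in the panel but absent for a sample
#' are treated downstream as t = 0, n = 0 (dropped-out sites), not an error.
#'
#' @param path path to the counts TSV.
#' @param panel optional [panel_fingerprint()] to validate against.
#' @return A `duplex_count_table`.
#' @export
read_counts <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "integer", "integer"),
                           col.names = c("sample_id", "site_id", "t", "n"),
                           check.names = FALSE, comment.char = "#",
                           quote = "", encoding = "UTF-8")
  duplex_count_table(raw$sample_id, raw$site_id, raw$t, raw$n, panel = panel)
}

#' Write a duplex count table to TSV
#'
#' Tab-delimited, UTF-8, newline-terminated, header `sample_id site_id t n`;
#' row order preserved so that `read_counts(write_counts(x)) == x`.
#'
#' @param tab a `duplex_count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(tab, path) {
  validate_counts(tab)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read/write sample metadata
#'
#' Sample metadata carries the experimental covariates of each plasma sample:
#' treatment arm (`control`/`primed`), priming agent (`liposome`, `antibody`,
#' `none`), dose in mg/kg, tumor-burden luminescence flux in photons/s,
#' drawn plasma volume in mL, a timepoint label, and — for synthetic cohorts
#' only — the true tumor fraction used by the generator.
#'
#' @param path TSV path with header `sample_id, arm, agent, dose_mg_per_kg,
#'   burden_flux, plasma_volume_ml, timepoint` and optional `true_fraction`.
#' @return A `sample_metadata` data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", encoding = "UTF-8")
  validate_sample_metadata(md)
}

#' @rdname read_sample_metadata
#' @param metadata a `sample_metadata` data.frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  validate_sample_metadata(metadata)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(as.data.frame(metadata), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname read_sample_metadata
#' @export
validate_sample_metadata <- function(metadata) {
  need <- c("sample_id", "arm", "agent", "dose_mg_per_kg", "burden_flux",
            "plasma_volume_ml", "timepoint")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) {
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicated sample_id in metadata", call. = FALSE)
  }
  if (!all(metadata$arm %in% c("control", "primed"))) {
    stop("arm must be 'control' or 'primed'", call. = FALSE)
  }
  if (!all(metadata$agent %in% c("liposome", "antibody", "none"))) {
    stop("agent must be 'liposome', 'antibody' or 'none'", call. = FALSE)
  }
  if (any(metadata$plasma_volume_ml <= 0)) {
    stop("plasma_volume_ml must be > 0", call. = FALSE)
  }
  if (any(metadata$burden_flux < 0) || any(metadata$dose_mg_per_kg < 0)) {
    stop("burden_flux and dose_mg_per_kg must be >= 0", call. = FALSE)
  }
  if ("true_fraction" %in% names(metadata)) {
    tf <- metadata$true_fraction[!is.na(metadata$true_fraction)]
    if (any(tf < 0 | tf > 1)) {
      stop("true_fraction must lie in [0, 1]", call. = FALSE)
    }
  }
  class(metadata) <- unique(c("sample_metadata", class(metadata)))
  metadata
}

#' Write/read a sensitivity estimate grid
#'
#' The grid schema is fixed: columns `panel_size, threshold, fraction, arm,
#' mean, se, n_replicates`. `fraction` is `NA` for grids computed at each
#' sample's observed tumor fraction.
#'
#' @param estimates a `sensitivity_grid` data.frame.
#' @param path output TSV path.
#' @return `path` (write) or the grid (read), invisibly for the writer.
#' @export
write_sensitivity <- function(estimates, path) {
  need <- c("panel_size", "threshold", "fraction", "arm", "mean", "se",
            "n_replicates")
  miss <- setdiff(need, names(estimates))
  if (length(miss)) {
    stop("sensitivity grid missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(as.data.frame(estimates)[, need], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_sensitivity
#' @export
read_sensitivity <- function(path) {
  grid <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, encoding = "UTF-8")
  if ("fraction" %in% names(grid)) grid$fraction <- as.numeric(grid$fraction)
  class(grid) <- unique(c("sensitivity_grid", class(grid)))
  grid
}

# Pivot a (possibly sparse) count table to sample x site matrices aligned to
# the panel order. Missing (sample, site) pairs become t = 0, n = 0, with a
# warning unless silent.
counts_to_matrices <- function(tab, panel, silent = FALSE) {
  samples <- unique(tab$sample_id)
  sites <- panel$site_id
  S <- length(sites)
  M <- length(samples)
  tmat <- matrix(0L, nrow = M, ncol = S, dimnames = list(samples, sites))
  nmat <- tmat
  i <- match(tab$sample_id, samples)
  j <- match(tab$site_id, sites)
  if (anyNA(j)) stop("count table contains sites not in panel", call. = FALSE)
  idx <- cbind(i, j)
  tmat[idx] <- tab$t
  nmat[idx] <- tab$n
  n_missing <- M * S - nrow(tab)
  if (n_missing > 0L && !silent) {
    warning(sprintf("%d (sample, site) pair(s) absent from count table; treated as t = 0, n = 0",
                    n_missing), call. = FALSE)
  }
  list(t = tmat, n = nmat, samples = samples, sites = sites)
}
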
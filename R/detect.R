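#' Classify one sample as ctDNA positive or negative
#'
#' A "distinct SNV detected" is a panel site with at least one mutant duplex
#' molecule (`n >= 1`). A sample is called ctDNA positive when the number of
#' distinct SNVs detected is greater than or equal to the threshold (weak
#' inequality; the canonical headline rule is `threshold = 2`, and the usual
#' stringency sweep is thresholds 2 through 10).
#'
#' @param n integer vector of mutant duplex counts, one per site.
#' @param t integer vector of total duplex counts, same length as `n`.
#' @param threshold integer >= 0 minimum number of distinct detected SNVs.
#' @param sample_id optional sample label carried into the result.
#' @return A one-row data.frame of class `detection_result` with columns
#'   `sample_id`, `snvs_detected`, `mutant_molecules`, `total_molecules`,
#'   `threshold`, `positive`. An empty sample (no sites) has
#'   `snvs_detected = 0` and is positive only when `threshold = 0`.
#' @export
#' @examples
#' detect_sample(n = c(0, 3, 1, 0), t = c(10, 10, 10, 10), threshold = 2)
detect_sample <- function(n, t, threshold = 2L, sample_id = NA_character_) {
  if (length(n) != length(t)) {
    stop("n and t must have equal length", call. = FALSE)
  }
  if (length(n) && (any(n < 0) || any(n > t))) {
    stop("require 0 <= n <= t at every site", call. = FALSE)
  }
  if (threshold < 0L) stop("threshold must be >= 0", call. = FALSE)
  snvs <- sum(n >= 1L)
  res <- data.frame(
    sample_id = sample_id,
    snvs_detected = as.integer(snvs),
    mutant_molecules = as.integer(sum(n)),
    total_molecules = as.integer(sum(t)),
    threshold = as.integer(threshold),
    positive = snvs >= threshold,
    stringsAsFactors = FALSE
  )
  class(res) <- c("detection_result", "data.frame")
  res
}

#' Classify every sample in a count table
#'
#' Applies [detect_sample()] to each sample in a duplex count table, one row
#' per (sample, threshold) combination.
#'
#' @param tab a [duplex_count_table()].
#' @param panel the bound [panel_fingerprint()]; sites missing for a sample
#'   count as t = 0, n = 0.
#' @param thresholds integer vector of SNV thresholds (default 2:10, the
#'   standard stringency sweep).
#' @return A `detection_result` data.frame.
#' @export
detect_samples <- function(tab, panel, thresholds = 2:10) {
  validate_counts(tab, panel)
  if (nrow(tab) == 0L) {
    res <- data.frame(sample_id = character(), snvs_detected = integer(),
                      mutant_molecules = integer(), total_molecules = integer(),
                      threshold = integer(), positive = logical())
    class(res) <- c("detection_result", "data.frame")
    return(res)
  }
  mats <- counts_to_matrices(tab, panel)
  snvs <- rowSums(mats$n >= 1L)
  mut <- rowSums(mats$n)
  tot <- rowSums(mats$t)
  out <- do.call(rbind, lapply(thresholds, function(k) {
    data.frame(sample_id = mats$samples,
               snvs_detected = as.integer(snvs),
               mutant_molecules = as.integer(mut),
               total_molecules = as.integer(tot),
               threshold = as.integer(k),
               positive = snvs >= k,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("detection_result", "data.frame")
  out
}

#' Group sensitivity
#'
#' Sensitivity is the fraction of samples in a group called ctDNA positive.
#' An empty group is a domain error, never a silent 0/0.
#'
#' @param positive logical vector of per-sample calls (or a
#'   `detection_result` at a single threshold).
#' @return Number in \[0, 1\].
#' @export
sensitivity <- function(positive) {
  if (is.data.frame(positive)) {
    if (length(unique(positive$threshold)) > 1L) {
      stop("detection results span multiple thresholds; filter to one first",
           call. = FALSE)
    }
    positive <- positive$positive
  }
  if (length(positive) == 0L) {
    stop("cannot compute sensitivity of an empty group", call. = FALSE)
  }
  mean(positive)
}

#' Stratify samples by tumor burden
#'
#' Tumor burden is measured as total luminescence flux (photons/s). The
#' standard strata are small (< 1.5e7), medium (1.5e7 to 1.5e8) and large
#' (> 1.5e8 photons/s).
#'
#' @param burden_flux numeric vector of fluxes in photons/s.
#' @param cutoffs two increasing cutoffs; defaults `c(1.5e7, 1.5e8)`.
#' @return Factor with levels `small`, `medium`, `large`.
#' @export
stratify_burden <- function(burden_flux, cutoffs = c(1.5e7, 1.5e8)) {
  if (length(cutoffs) != 2L || diff(cutoffs) <= 0) {
    stop("cutoffs must be two increasing values", call. = FALSE)
  }
  cut(burden_flux, breaks = c(-Inf, cutoffs, Inf),
      labels = c("small", "medium", "large"), right = TRUE)
}

#' Burden-stratified sensitivity table
#'
#' Computes sensitivity per (burden stratum, arm, threshold), mirroring the
#' standard low/medium/high tumor-burden readout of a priming-agent study.
#'
#' @param detections a `detection_result` from [detect_samples()].
#' @param metadata a `sample_metadata` data.frame.
#' @param cutoffs burden flux cutoffs, see [stratify_burden()].
#' @return data.frame with columns `stratum, arm, threshold, sensitivity,
#'   n_samples`. Empty strata are omitted (not reported as 0/0).
#' @export
sensitivity_by_burden <- function(detections, metadata,
                                  cutoffs = c(1.5e7, 1.5e8)) {
  metadata <- validate_sample_metadata(metadata)
  m <- match(detections$sample_id, metadata$sample_id)
  if (anyNA(m)) {
    stop("detection results contain samples absent from metadata",
         call. = FALSE)
  }
  stratum <- stratify_burden(metadata$burden_flux[m], cutoffs)
  arm <- metadata$arm[m]
  agg <- stats::aggregate(
    detections$positive,
    by = list(stratum = stratum, arm = arm, threshold = detections$threshold),
    FUN = function(p) c(sens = mean(p), n = length(p))
  )
  out <- data.frame(stratum = agg$stratum, arm = agg$arm,
                    threshold = agg$threshold,
                    sensitivity = agg$x[, "sens"],
                    n_samples = as.integer(agg$x[, "n"]))
  out[order(out$stratum, out$arm, out$threshold), , drop = FALSE]
}

#' Maximum-likelihood tumor fraction estimate
#'
#' Under the binomial generative model `n_ij ~ Binomial(t_ij, f_i)` the MLE of
#' the global tumor fraction of sample i is the pooled mutant rate
#' `f_hat = sum_j n_ij / sum_j t_ij`.
#'
#' @param n,t mutant and total duplex counts over the panel for one sample.
#' @return `f_hat` in \[0, 1\]; `NA_real_` (with a warning) when `sum(t) = 0`,
#'   where the fraction is undefined.
#' @export
estimate_tumor_fraction <- function(n, t) {
  if (length(n) != length(t)) stop("n and t must have equal length",
                                   call. = FALSE)
  if (length(n) && (any(n < 0) || any(n > t))) {
    stop("require 0 <= n <= t at every site", call. = FALSE)
  }
  tt <- sum(as.numeric(t))
  if (tt == 0) {
    warning("total duplex count is zero; tumor fraction undefined",
            call. = FALSE)
    return(NA_real_)
  }
  sum(as.numeric(n)) / tt
}

#' Tumor fraction estimates for every sample in a table
#'
#' @param tab a [duplex_count_table()].
#' @return data.frame `sample_id, f_hat, mutant_molecules, total_molecules`.
#' @export
estimate_tumor_fractions <- function(tab) {
  validate_counts(tab)
  if (nrow(tab) == 0L) {
    return(data.frame(sample_id = character(), f_hat = numeric(),
                      mutant_molecules = numeric(), total_molecules = numeric()))
  }
  mut <- tapply(as.numeric(tab$n), tab$sample_id, sum)
  tot <- tapply(as.numeric(tab$t), tab$sample_id, sum)
  ids <- unique(tab$sample_id)   # preserve first-appearance order
  mut <- mut[ids]; tot <- tot[ids]
  f <- ifelse(tot > 0, mut / tot, NA_real_)
  if (anyNA(f)) {
    warning("tumor fraction undefined (zero total depth) for sample(s): ",
            paste(ids[is.na(f)], collapse = ", "), call. = FALSE)
  }
  data.frame(sample_id = ids, f_hat = as.numeric(f),
             mutant_molecules = as.numeric(mut),
             total_molecules = as.numeric(tot), row.names = NULL)
}

#' Relative duplex depth (per-library z-scores)
#'
#' Normalizes per-site duplex depths within one library by subtracting the
#' library's mean depth and dividing by its standard deviation. The population
#' (n-denominator) standard deviation is used: the normalization is
#' descriptive, and this keeps results bit-reproducible without a sample-size
#' correction.
#'
#' @param t numeric vector of per-site depths for one library, length >= 2.
#' @return z-scores with mean 0 and population SD 1; all zeros (with a
#'   warning) when the depths have zero variance.
#' @export
#' @examples
#' relative_duplex_depth(c(10, 20, 30))  # -1.2247, 0, 1.2247
relative_duplex_depth <- function(t) {
  t <- as.numeric(t)
  if (length(t) < 2L || anyNA(t) || any(!is.finite(t))) {
    stop("need >= 2 finite depths", call. = FALSE)
  }
  mu <- mean(t)
  sd_pop <- sqrt(mean((t - mu)^2))
  if (sd_pop == 0) {
    warning("zero depth variance; returning all-zero relative depths",
            call. = FALSE)
    return(rep(0, length(t)))
  }
  (t - mu) / sd_pop
}

#' Percentage of probe remaining over time
#'
#' Pharmacokinetic readout: percentage of a labeled mononucleosome probe
#' remaining in circulation at 60 minutes relative to 1 minute.
#'
#' @param conc_at_60min,conc_at_1min non-negative concentrations;
#'   `conc_at_1min` must be > 0.
#' @return `100 * conc_at_60min / conc_at_1min`.
#' @export
percent_remaining <- function(conc_at_60min, conc_at_1min) {
  if (any(conc_at_1min <= 0)) {
    stop("reference (1 min) concentration must be > 0", call. = FALSE)
  }
  if (any(conc_at_60min < 0)) stop("concentrations must be >= 0", call. = FALSE)
  100 * conc_at_60min / conc_at_1min
}

#' Group fold change
#'
#' Ratio of a location statistic between two groups, e.g. the median mutant
#' molecule count in the primed arm over the control arm.
#'
#' @param primed,control numeric vectors of group measurements.
#' @param stat summary function, default [stats::median].
#' @return `stat(primed) / stat(control)`.
#' @export
fold_change <- function(primed, control, stat = stats::median) {
  denom <- stat(control)
  if (!is.finite(denom) || denom == 0) {
    stop("control group summary is zero or non-finite; fold change undefined",
         call. = FALSE)
  }
  stat(primed) / denom
}
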
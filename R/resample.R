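#' Resampling plan
#'
#' Configuration of the two down-scaling procedures: bootstrap panel-size
#' downsampling and binomial tumor-fraction downscaling.
#'
#' @param panel_sizes integer panel sizes >= 1 to resample down to.
#' @param thresholds integer SNV thresholds >= 0 (default 2:10).
#' @param fractions target tumor fractions in \[0, 1\] for
#'   [downscale_fraction()], or `"observed"` to keep each sample's own
#'   estimated fraction.
#' @param n_replicates replicates per grid point (study default 100; >= 2 so
#'   a spread is defined).
#' @param seed integer master seed.
#' @param replace logical; sites are drawn with replacement (the faithful
#'   bootstrap, default) or without.
#' @param se_type `"sd"` (default): SE is the standard deviation of the
#'   replicate sensitivities, i.e. the spread of the bootstrap distribution;
#'   `"sd_over_sqrt_r"`: that SD divided by `sqrt(n_replicates)`.
#' @return An object of class `resampling_plan`.
#' @export
resampling_plan <- function(panel_sizes,
                            thresholds = 2:10,
                            fractions = "observed",
                            n_replicates = 100L,
                            seed = 1L,
                            replace = TRUE,
                            se_type = c("sd", "sd_over_sqrt_r")) {
  se_type <- match.arg(se_type)
  if (length(panel_sizes) < 1L || any(panel_sizes < 1L)) {
    stop("panel_sizes must be integers >= 1", call. = FALSE)
  }
  if (any(thresholds < 0L)) stop("thresholds must be >= 0", call. = FALSE)
  if (!identical(fractions, "observed")) {
    fractions <- as.numeric(fractions)
    if (any(is.na(fractions) | fractions < 0 | fractions > 1)) {
      stop("fractions must lie in [0, 1] (or be \"observed\")", call. = FALSE)
    }
  }
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  plan <- list(panel_sizes = sort(unique(as.integer(panel_sizes))),
               thresholds = sort(unique(as.integer(thresholds))),
               fractions = fractions,
               n_replicates = as.integer(n_replicates),
               seed = as.integer(seed),
               replace = isTRUE(replace),
               se_type = se_type)
  class(plan) <- "resampling_plan"
  plan
}

# Sensitivity per (arm, threshold) from a detected-SNV count vector.
# Returns matrix thresholds x arms.
sens_by_arm <- function(snvs, arm, thresholds, arms) {
  vapply(arms, function(a) {
    s <- snvs[arm == a]
    vapply(thresholds, function(k) mean(s >= k), numeric(1))
  }, numeric(length(thresholds)))
}

summarize_replicates <- function(reps, se_type, n_replicates) {
  m <- mean(reps)
  s <- stats::sd(reps)
  if (se_type == "sd_over_sqrt_r") s <- s / sqrt(n_replicates)
  c(mean = m, se = s)
}

#' Bootstrap panel-size downsampling
#'
#' Estimates sensitivity at smaller panel sizes by bootstrap: for each
#' replicate, `panel_size` site ids are drawn (with replacement by default)
#' from the full panel; the same drawn site multiset is applied to every
#' sample so within-replicate arm comparisons share a common panel. The
#' detected-SNV count on a resampled multiset counts a duplicated detected
#' site once per duplicate — the faithful with-replacement bootstrap, which
#' differs from subsampling without replacement (`replace = FALSE` is
#' available for comparison). Sensitivity is recomputed per (panel size,
#' threshold, arm); the mean and SE over replicates are reported, where SE is
#' by default the SD of the replicate sensitivities.
#'
#' @param tab a [duplex_count_table()].
#' @param metadata `sample_metadata` covering all samples in `tab`.
#' @param panel the bound [panel_fingerprint()].
#' @param plan a [resampling_plan()]; `fractions` is ignored here (observed
#'   mutant counts are used as-is).
#' @return A `sensitivity_grid` data.frame with columns `panel_size,
#'   threshold, fraction (NA), arm, mean, se, n_replicates`.
#' @export
downsample_panel <- function(tab, metadata, panel, plan) {
  validate_counts(tab, panel)
  metadata <- validate_sample_metadata(metadata)
  if (nrow(tab) == 0L) stop("count table is empty", call. = FALSE)
  S <- nrow(panel)
  if (any(plan$panel_sizes > S)) {
    stop("panel_sizes exceed the full panel size (", S, ")", call. = FALSE)
  }
  mats <- counts_to_matrices(tab, panel, silent = TRUE)
  det <- mats$n >= 1L  # samples x sites detection indicator
  arm <- metadata$arm[match(mats$samples, metadata$sample_id)]
  if (anyNA(arm)) stop("count table contains samples absent from metadata",
                       call. = FALSE)
  arms <- unique(arm)
  R <- plan$n_replicates
  with_seed(plan$seed, {
    out <- list()
    for (ps in plan$panel_sizes) {
      # reps: array [threshold, arm, replicate]
      reps <- array(NA_real_,
                    dim = c(length(plan$thresholds), length(arms), R))
      for (r in seq_len(R)) {
        idx <- sample.int(S, ps, replace = plan$replace)
        snvs <- if (plan$replace) {
          # duplicates count once per occurrence
          as.numeric(det[, idx, drop = FALSE] %*% rep(1, ps))
        } else {
          rowSums(det[, idx, drop = FALSE])
        }
        reps[, , r] <- sens_by_arm(snvs, arm, plan$thresholds, arms)
      }
      for (ai in seq_along(arms)) {
        for (ki in seq_along(plan$thresholds)) {
          ms <- summarize_replicates(reps[ki, ai, ], plan$se_type, R)
          out[[length(out) + 1L]] <- data.frame(
            panel_size = ps, threshold = plan$thresholds[ki],
            fraction = NA_real_, arm = arms[ai],
            mean = ms[["mean"]], se = ms[["se"]], n_replicates = R,
            stringsAsFactors = FALSE)
        }
      }
    }
    grid <- do.call(rbind, out)
    class(grid) <- unique(c("sensitivity_grid", class(grid)))
    grid
  })
}

#' Binomial tumor-fraction downscaling
#'
#' Estimates sensitivity at tumor fractions lower than those observed: holding
#' each sample's observed per-site total duplex counts `t_ij` fixed, mutant
#' counts are regenerated per replicate as `n_ij ~ Binomial(t_ij, f_target)`,
#' then the SNV-threshold classifier and group sensitivity are applied. Panel
#' sizes in the plan are combined with fraction downscaling by drawing one
#' site multiset per (replicate, panel size), shared across samples, exactly
#' as in [downsample_panel()]. Warns when a target fraction exceeds a
#' sample's estimated fraction (upscaling is extrapolation beyond the
#' observed data).
#'
#' @inheritParams downsample_panel
#' @param plan a [resampling_plan()]; `fractions` must be numeric here.
#' @return A `sensitivity_grid` over (fraction, panel size, threshold, arm).
#' @export
downscale_fraction <- function(tab, metadata, panel, plan) {
  validate_counts(tab, panel)
  metadata <- validate_sample_metadata(metadata)
  if (identical(plan$fractions, "observed")) {
    stop("downscale_fraction needs numeric plan$fractions", call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("count table is empty", call. = FALSE)
  S <- nrow(panel)
  if (any(plan$panel_sizes > S)) {
    stop("panel_sizes exceed the full panel size (", S, ")", call. = FALSE)
  }
  mats <- counts_to_matrices(tab, panel, silent = TRUE)
  arm <- metadata$arm[match(mats$samples, metadata$sample_id)]
  if (anyNA(arm)) stop("count table contains samples absent from metadata",
                       call. = FALSE)
  arms <- unique(arm)
  fhat <- estimate_tumor_fractions(tab)
  fmax <- max(fhat$f_hat, na.rm = TRUE)
  over <- plan$fractions[plan$fractions > fmax]
  if (length(over)) {
    warning("target fraction(s) exceed every sample's estimated fraction (",
            signif(fmax, 3), "): ", paste(signif(over, 3), collapse = ", "),
            "; results are extrapolations", call. = FALSE)
  }
  tvec <- as.vector(mats$t)
  M <- nrow(mats$t)
  R <- plan$n_replicates
  with_seed(plan$seed, {
    out <- list()
    for (f in plan$fractions) {
      reps <- array(NA_real_, dim = c(length(plan$thresholds), length(arms),
                                      length(plan$panel_sizes), R))
      for (r in seq_len(R)) {
        nmat <- matrix(stats::rbinom(length(tvec), tvec, f), nrow = M)
        det <- nmat >= 1L
        for (pi in seq_along(plan$panel_sizes)) {
          ps <- plan$panel_sizes[pi]
          snvs <- if (ps == S && !plan$replace) {
            rowSums(det)
          } else {
            idx <- sample.int(S, ps, replace = plan$replace)
            if (plan$replace) {
              as.numeric(det[, idx, drop = FALSE] %*% rep(1, ps))
            } else {
              rowSums(det[, idx, drop = FALSE])
            }
          }
          reps[, , pi, r] <- sens_by_arm(snvs, arm, plan$thresholds, arms)
        }
      }
      for (pi in seq_along(plan$panel_sizes)) {
        for (ai in seq_along(arms)) {
          for (ki in seq_along(plan$thresholds)) {
            ms <- summarize_replicates(reps[ki, ai, pi, ], plan$se_type, R)
            out[[length(out) + 1L]] <- data.frame(
              panel_size = plan$panel_sizes[pi],
              threshold = plan$thresholds[ki],
              fraction = f, arm = arms[ai],
              mean = ms[["mean"]], se = ms[["se"]], n_replicates = R,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    grid <- do.call(rbind, out)
    class(grid) <- unique(c("sensitivity_grid", class(grid)))
    grid
  })
}

#' Parametric-bootstrap check of the binomial count model
#'
#' Tests, per sample, whether the observed per-site mutant counts are
#' consistent with `n_ij ~ Binomial(t_ij, f_i)` at a single global fraction
#' `f_i = f_hat = sum(n)/sum(t)`. The statistic is a variance-stabilized
#' Pearson-type discrepancy
#' `T = sum_j (n_j - t_j * f_hat)^2 / (t_j * f_hat * (1 - f_hat) + eps)`;
#' its null distribution is obtained by a parametric bootstrap (simulate
#' `n* ~ Binomial(t, f_hat)`, re-estimate `f_hat*`, recompute `T*`), giving a
#' resampling p-value `(1 + #(T* >= T)) / (B + 1)`. Samples with zero total
#' depth are skipped with a warning. Overdispersed alternatives — e.g. a
#' hot-spot site at much higher allele fraction than the rest — inflate `T`
#' and yield small p-values.
#'
#' @param tab a [duplex_count_table()].
#' @param panel the bound [panel_fingerprint()].
#' @param n_boot parametric bootstrap replicates per sample (default 199).
#' @param seed integer seed.
#' @return data.frame of class `model_check_report`: `sample_id, f_hat,
#'   n_sites, statistic, p_value, skipped`.
#' @export
binomial_model_check <- function(tab, panel, n_boot = 199L, seed = 1L) {
  validate_counts(tab, panel)
  if (nrow(tab) == 0L) stop("count table is empty", call. = FALSE)
  mats <- counts_to_matrices(tab, panel, silent = TRUE)
  eps <- 1e-12
  chisq_stat <- function(n, t, f) {
    sum((n - t * f)^2 / (t * f * (1 - f) + eps))
  }
  with_seed(seed, {
    rows <- lapply(seq_along(mats$samples), function(i) {
      t <- as.numeric(mats$t[i, ])
      n <- as.numeric(mats$n[i, ])
      tt <- sum(t)
      if (tt == 0) {
        warning("sample ", mats$samples[i],
                " has zero total depth; skipped in model check",
                call. = FALSE)
        return(data.frame(sample_id = mats$samples[i], f_hat = NA_real_,
                          n_sites = length(t), statistic = NA_real_,
                          p_value = NA_real_, skipped = TRUE,
                          stringsAsFactors = FALSE))
      }
      f <- sum(n) / tt
      obs <- chisq_stat(n, t, f)
      null <- vapply(seq_len(n_boot), function(b) {
        ns <- stats::rbinom(length(t), t, f)
        fs <- sum(ns) / tt
        chisq_stat(ns, t, fs)
      }, numeric(1))
      data.frame(sample_id = mats$samples[i], f_hat = f,
                 n_sites = length(t), statistic = obs,
                 p_value = (1 + sum(null >= obs)) / (n_boot + 1),
                 skipped = FALSE, stringsAsFactors = FALSE)
    })
    rep <- do.call(rbind, rows)
    class(rep) <- unique(c("model_check_report", class(rep)))
    rep
  })
}
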
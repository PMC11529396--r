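# Shared fixtures and independent oracles for the test suite. Oracles here
# never call the code paths they check.

toy_panel <- function(n = 3L, name = "toy") {
  panel_fingerprint(chrom = rep("chr1", n),
                    pos = seq_len(n) * 10L,
                    ref_allele = rep(c("A", "C"), length.out = n),
                    alt_allele = rep(c("T", "G"), length.out = n),
                    site_id = sprintf("s%02d", seq_len(n)),
                    name = name)
}

toy_counts <- function(panel, sample_ids, t, n) {
  duplex_count_table(
    sample_id = rep(sample_ids, each = nrow(panel)),
    site_id = rep(panel$site_id, times = length(sample_ids)),
    t = t, n = n, panel = panel)
}

toy_metadata <- function(sample_ids, arm = "control", burden = 1e6,
                         true_fraction = NULL) {
  md <- data.frame(sample_id = sample_ids,
                   arm = rep(arm, length.out = length(sample_ids)),
                   agent = ifelse(rep(arm, length.out = length(sample_ids)) ==
                                    "primed", "antibody", "none"),
                   dose_mg_per_kg = 0,
                   burden_flux = rep(burden, length.out = length(sample_ids)),
                   plasma_volume_ml = 0.33,
                   timepoint = "post",
                   stringsAsFactors = FALSE)
  if (!is.null(true_fraction)) md$true_fraction <- true_fraction
  md
}

# Exhaustive-enumeration oracle for the Poisson-binomial tail: sums the
# probability of every one of the 2^S detection outcomes. Independent of the
# package's DP convolution.
enum_detection_probability <- function(t, f, threshold) {
  p <- 1 - (1 - f)^t
  S <- length(t)
  total <- 0
  for (m in 0:(2^S - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(S)]
    if (sum(bits) >= threshold) {
      total <- total + prod(ifelse(bits == 1L, p, 1 - p))
    }
  }
  total
}

# Monte-Carlo sensitivity through the package's generative + classifier path:
# R pseudo-samples with fixed per-site depths t, fraction f. Returns the
# detected-SNV count per pseudo-sample.
mc_detected_counts <- function(t, f, R) {
  tm <- matrix(rep(as.integer(t), each = R), nrow = R)
  n <- simulate_mutants(tm, f)
  rowSums(n >= 1L)
}

# Brute-force expectation of bootstrap sensitivity over resampled site
# multisets: direct resampling loop, independent of downsample_panel.
brute_bootstrap_sensitivity <- function(det, panel_size, threshold, n_draws,
                                        seed) {
  S <- ncol(det)
  set.seed(seed)
  mean(vapply(seq_len(n_draws), function(r) {
    idx <- sample.int(S, panel_size, replace = TRUE)
    mean(rowSums(det[, idx, drop = FALSE]) >= threshold)
  }, numeric(1)))
}

# Exact expectation of with-replacement bootstrap sensitivity at panel size m:
# each of the m picks is iid uniform over sites, so the number of detected
# picks for sample i is Binomial(m, q_i) with q_i = detected fraction of the
# panel. Closed form via pbinom; independent of the bootstrap code.
exact_bootstrap_sensitivity <- function(det, panel_size, threshold) {
  q <- rowMeans(det)
  mean(stats::pbinom(threshold - 1L, panel_size, q, lower.tail = FALSE))
}
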
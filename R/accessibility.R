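#' Normalize a per-peak count matrix for differential accessibility
#'
#' Counts-per-million scaling per sample followed by `log2(x + 1)` — a
#' transparent, library-size-aware transform on which the per-peak test
#' operates. Scale-invariant: doubling all counts and library sizes
#' leaves the result unchanged.
#'
#' @param counts peaks x samples matrix of non-negative counts.
#' @param library_sizes per-sample totals; default the column sums.
#' @return normalized matrix (same dimensions).
#' @export
normalize_counts <- function(counts, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  cpm <- sweep(counts, 2, library_sizes / 1e6, "/")
  log2(cpm + 1)
}

#' Call differentially accessible regions on a normalized count matrix
#'
#' Per-peak two-group comparison on CPM/log2-normalized values with BH
#' adjustment across peaks; a peak is significant when its q-value is
#' strictly below `fdr_max` (default 0.05). The default engine is limma's
#' moderated t-statistic (empirical-Bayes variance shrinkage across
#' peaks, `trend = TRUE`), the standard choice at ATAC replicate numbers
#' where per-peak variances are estimated on a handful of degrees of
#' freedom; `engine = "t"` gives the unmoderated per-peak t-test.
#'
#' @param counts peaks x samples raw count matrix.
#' @param group_a,group_b column names or indices of the two groups
#'   (at least 2 replicates each).
#' @param fdr_max q-value cutoff (strict `<`), default 0.05.
#' @param library_sizes optional per-sample totals for normalization.
#' @param engine `"limma"` (moderated t, default) or `"t"` (plain
#'   pooled-variance t).
#' @return tibble: `peak_id`, `mean_a`, `mean_b`, `log2_fold_change` (on
#'   the normalized scale, B minus A), `p_value`, `q_value`, `direction`,
#'   `significant`.
#' @export
call_dars <- function(counts, group_a, group_b, fdr_max = 0.05,
                      library_sizes = colSums(counts),
                      engine = c("limma", "t")) {
  engine <- match.arg(engine)
  counts <- as.matrix(counts)
  norm <- normalize_counts(counts, library_sizes)
  idx_a <- resolve_samples(norm, group_a)
  idx_b <- resolve_samples(norm, group_b)
  if (length(idx_a) < 2 || length(idx_b) < 2)
    stop("need at least 2 replicates per group")
  if (engine == "limma") {
    design <- cbind(intercept = 1,
                    b_vs_a = c(rep(0, length(idx_a)), rep(1, length(idx_b))))
    fit <- limma::eBayes(limma::lmFit(norm[, c(idx_a, idx_b), drop = FALSE],
                                      design), trend = TRUE)
    p <- fit$p.value[, "b_vs_a"]
    tt <- list(mean_a = unname(rowMeans(norm[, idx_a, drop = FALSE])),
               mean_b = unname(rowMeans(norm[, idx_b, drop = FALSE])),
               p = unname(as.numeric(p)))
  } else {
    tt <- row_t_test(norm, idx_a, idx_b, var_equal = TRUE)
  }
  q <- bh_fdr(tt$p)
  tibble::tibble(
    peak_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    mean_a = tt$mean_a,
    mean_b = tt$mean_b,
    log2_fold_change = tt$mean_b - tt$mean_a,
    p_value = tt$p,
    q_value = q,
    direction = ifelse(tt$mean_b >= tt$mean_a, "up", "down"),
    significant = q < fdr_max
  )
}

#' Percentage of differential peaks in a given direction
#'
#' @param n_down count of peaks in the direction of interest.
#' @param n_total total significant peaks (> 0).
#' @return percentage, 1 decimal, half-up.
#' @export
dar_direction_fraction <- function(n_down, n_total) {
  if (n_total <= 0) stop("n_total must be > 0")
  if (n_down > n_total) stop("n_down cannot exceed n_total")
  overlap_fraction(n_down, n_total)
}

#' Expected differential peaks per chromatin-state cluster, with
#' enrichment tests
#'
#' The expected count for a cluster is the total number of significantly
#' regulated peaks multiplied by that cluster's share of all peaks. Each
#' cluster's observed count is tested against the others with a one-sided
#' (greater) Fisher exact test on the 2x2 table
#' (in-cluster vs not) x (significant vs not).
#'
#' @param observed named integer vector: significant peaks per cluster.
#' @param cluster_sizes named integer vector: total peaks per cluster
#'   (same names as `observed`).
#' @return tibble: `cluster`, `n_peaks`, `proportion`, `observed`,
#'   `expected` (unrounded), `enrichment` (observed/expected),
#'   `p_value`.
#' @export
expected_cluster_dars <- function(observed, cluster_sizes) {
  if (is.null(names(observed)) || is.null(names(cluster_sizes)))
    stop("observed and cluster_sizes must be named")
  if (!setequal(names(observed), names(cluster_sizes)))
    stop("cluster names must match between observed and cluster_sizes")
  observed <- observed[names(cluster_sizes)]
  if (any(observed > cluster_sizes))
    stop("observed significant peaks exceed cluster size")
  prop <- cluster_sizes / sum(cluster_sizes)
  if (abs(sum(prop) - 1) > 1e-9) stop("proportions must sum to 1")
  n_sig <- sum(observed)
  n_tot <- sum(cluster_sizes)
  expected <- n_sig * prop
  p <- vapply(names(cluster_sizes), function(cl) {
    n11 <- observed[[cl]]
    n12 <- cluster_sizes[[cl]] - n11
    n21 <- n_sig - n11
    n22 <- (n_tot - cluster_sizes[[cl]]) - n21
    fisher_overlap_test(n11, n12, n21, n22)
  }, numeric(1))
  tibble::tibble(
    cluster = names(cluster_sizes),
    n_peaks = as.integer(cluster_sizes),
    proportion = as.numeric(prop),
    observed = as.integer(observed),
    expected = as.numeric(expected),
    enrichment = ifelse(expected > 0, observed / expected, NA_real_),
    p_value = as.numeric(p)
  )
}
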
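#' Construct an expression matrix container
#'
#' Wraps a genes x samples RPKM/FPKM matrix with its quantification type
#' and a flag tracking whether the low-expression pseudocount has been
#' applied (it may be applied at most once).
#'
#' @param values numeric matrix, genes x samples, non-negative.
#' @param quant_type `"single_end_RPKM"` or `"paired_end_FPKM"`; decides
#'   the pseudocount (+0.1 vs +1).
#' @param metadata optional tibble of per-sample metadata (condition, day,
#'   replicate), one row per column of `values`.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values,
                              quant_type = c("paired_end_FPKM",
                                             "single_end_RPKM"),
                              metadata = NULL) {
  quant_type <- match.arg(quant_type)
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be non-negative")
  if (!is.null(metadata) && nrow(metadata) != ncol(values))
    stop("metadata must have one row per sample")
  structure(list(values = values, quant_type = quant_type,
                 metadata = metadata, pseudocount_applied = FALSE),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ",
      ncol(x$values), " samples (", x$quant_type,
      if (x$pseudocount_applied) ", pseudocounted" else "", ")\n", sep = "")
  invisible(x)
}

#' Apply the low-expression pseudocount once
#'
#' Adds +0.1 to single-end RPKM values and +1 to paired-end FPKM values,
#' damping the influence of low-expression genes on ratios. Calling it a
#' second time on the same matrix is an error.
#'
#' @param x an [expression_matrix()].
#' @return the matrix with the pseudocount applied and the flag set.
#' @export
add_pseudocount <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$pseudocount_applied)
    stop("pseudocount already applied to this matrix")
  pc <- if (x$quant_type == "single_end_RPKM") 0.1 else 1
  x$values <- x$values + pc
  x$pseudocount_applied <- TRUE
  x
}

#' Remove genes with very low expression
#'
#' Drops genes whose mean over samples of `log2(FPKM + 1)` is strictly
#' below 1 — the filter used before cross-dataset expression comparisons
#' where low capture rates would otherwise dominate.
#'
#' @param x an [expression_matrix()] on the FPKM scale, pseudocount not yet
#'   applied (the +1 here is part of the filter's log transform).
#' @return the filtered `expression_matrix`.
#' @export
low_expression_filter <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$pseudocount_applied)
    stop("apply the low-expression filter before the pseudocount")
  keep <- rowMeans(log2(x$values + 1)) >= 1
  x$values <- x$values[keep, , drop = FALSE]
  x
}

# vectorized pooled-variance (or Welch) two-sided t-test across rows
row_t_test <- function(values, idx_a, idx_b, var_equal = TRUE) {
  a <- values[, idx_a, drop = FALSE]
  b <- values[, idx_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (mb - ma) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # both groups constant: no evidence either way -> p = 1 by convention
  degenerate <- se == 0 | !is.finite(se)
  p[degenerate & (ma == mb)] <- 1
  p[degenerate & (ma != mb)] <- 0
  list(mean_a = unname(ma), mean_b = unname(mb), t = unname(tstat),
       df = unname(df), p = unname(p))
}

#' Call differentially expressed genes by t-test and fold change
#'
#' Unpaired two-sided t-test (pooled variance by default, Welch by flag)
#' on pseudocounted expression values, with fold change computed as
#' `mean_B / mean_A` of those values. A gene is significant when
#' `p < p_max` and the fold change exceeds `fc_min` in either direction.
#'
#' @param x an [expression_matrix()] with the pseudocount applied.
#' @param group_a,group_b column names (or indices) of the two groups,
#'   at least 2 replicates each.
#' @param p_max p-value threshold (strict `<`), default 0.05.
#' @param fc_min fold-change threshold (strict `>`), default 2.
#' @param var_equal pooled-variance t (default) vs Welch.
#' @return tibble: `gene_id`, `mean_a`, `mean_b`, `fold_change`,
#'   `log2_fold_change`, `p_value`, `direction`, `significant`.
#' @export
call_degs <- function(x, group_a, group_b, p_max = 0.05, fc_min = 2,
                      var_equal = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!x$pseudocount_applied)
    stop("apply the pseudocount before calling DEGs")
  idx_a <- resolve_samples(x$values, group_a)
  idx_b <- resolve_samples(x$values, group_b)
  if (length(idx_a) < 2 || length(idx_b) < 2)
    stop("need at least 2 replicates per group")
  tt <- row_t_test(x$values, idx_a, idx_b, var_equal = var_equal)
  fc <- tt$mean_b / tt$mean_a
  tibble::tibble(
    gene_id = rownames(x$values) %||% as.character(seq_len(nrow(x$values))),
    mean_a = tt$mean_a,
    mean_b = tt$mean_b,
    fold_change = fc,
    log2_fold_change = log2(fc),
    p_value = tt$p,
    direction = ifelse(fc >= 1, "up", "down"),
    significant = tt$p < p_max & (fc > fc_min | fc < 1 / fc_min)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_samples <- function(values, group) {
  if (is.character(group)) {
    idx <- match(group, colnames(values))
    if (anyNA(idx)) stop("unknown sample id(s): ",
                         paste(group[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(group)
}

#' Fraction of state-specific genes responding during repriming
#'
#' Given the number of state-specific DEGs and how many of them respond
#' significantly in the expected direction during the naive-to-primed
#' transition, returns the percentage (1 decimal, half-up). When two
#' DegTables are supplied instead of counts, the responding subset is
#' computed: genes significant in both tables with the response direction
#' matching `direction`.
#'
#' @param total count of state-specific DEGs, or a DegTable from
#'   [call_degs()] defining the state-specific set (significant rows).
#' @param responding count of responders, or a DegTable for the repriming
#'   contrast.
#' @param direction `"down"` or `"up"`: required repriming response
#'   direction (used only with DegTable inputs).
#' @return list: `percent`, `n_total`, `n_responding`, and `genes` when
#'   computed from tables.
#' @export
repriming_response_fraction <- function(total, responding,
                                        direction = c("down", "up")) {
  if (is.numeric(total) && is.numeric(responding)) {
    if (total <= 0) stop("total must be > 0")
    if (responding > total) stop("responding cannot exceed total")
    return(list(percent = overlap_fraction(responding, total),
                n_total = total, n_responding = responding))
  }
  direction <- match.arg(direction)
  state_genes <- total$gene_id[total$significant]
  if (length(state_genes) == 0) stop("total must be > 0")
  resp <- responding[responding$significant &
                       responding$direction == direction, ]
  genes <- intersect(state_genes, resp$gene_id)
  list(percent = overlap_fraction(length(genes), length(state_genes)),
       n_total = length(state_genes), n_responding = length(genes),
       genes = sort(genes))
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test between groups
#'
#' Exact for small samples without ties, normal approximation with tie
#' correction otherwise (the standard `wilcox.test` behavior).
#'
#' @param values_a,values_b numeric vectors, both non-empty.
#' @return two-sided p-value.
#' @export
mann_whitney_group_test <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("both groups must be non-empty")
  suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = length(values_a) <= 8 &&
                         length(values_b) <= 8 &&
                         !anyDuplicated(c(values_a, values_b)))$p.value
  )
}
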
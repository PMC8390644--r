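#' @importFrom rlang .data
#' @import tibble
NULL

#' Filter AP-MS identifications by search-engine quality and known contaminants
#'
#' Retains records with identification score strictly above `score_min`,
#' peptide count strictly above `peptide_min`, and a protein id not on the
#' common-contaminant list (trypsin, keratins, actins, tubulins in a real
#' run). Duplicate records for a protein within an experiment are collapsed
#' to the one with the highest bait counts before filtering.
#'
#' @param records tibble with columns `protein_id`, `experiment_id`,
#'   `bait_counts`, `control_counts`, `identification_score`, `n_peptides`.
#' @param score_min identification-score threshold (strict `>`), default 10.
#' @param peptide_min peptide-count threshold (strict `>`), default 2.
#' @param contaminant_ids character vector of protein ids to drop outright.
#' @return filtered records tibble.
#' @export
filter_identifications <- function(records, score_min = 10, peptide_min = 2,
                                   contaminant_ids = character()) {
  check_spectral_records(records)
  if (score_min < 0 || peptide_min < 0) stop("thresholds must be non-negative")
  records |>
    dplyr::group_by(.data$protein_id, .data$experiment_id) |>
    dplyr::slice_max(.data$bait_counts, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(
      .data$identification_score > score_min,
      .data$n_peptides > peptide_min,
      !.data$protein_id %in% contaminant_ids
    )
}

#' Keep proteins detected in enough replicate experiments
#'
#' A protein must survive identification filtering in at least
#' `min_experiments` of the `total_experiments` replicate IPs to be an
#' interactor candidate (default: three of four).
#'
#' @param records filtered records (see [filter_identifications()]).
#' @param min_experiments minimum distinct experiments, default 3.
#' @param total_experiments roster size, default 4.
#' @return character vector of protein ids passing the detection gate.
#' @export
detection_filter <- function(records, min_experiments = 3,
                             total_experiments = 4) {
  check_spectral_records(records)
  if (min_experiments > total_experiments)
    stop("min_experiments cannot exceed total_experiments")
  n_exp <- length(unique(records$experiment_id))
  if (n_exp > total_experiments)
    stop("records contain more experiments (", n_exp,
         ") than the declared roster (", total_experiments, ")")
  tab <- records |>
    dplyr::distinct(.data$protein_id, .data$experiment_id) |>
    dplyr::count(.data$protein_id)
  sort(tab$protein_id[tab$n >= min_experiments])
}

#' Remove frequent contaminants by CRAPome-style frequency
#'
#' Proteins observed in strictly more than `max_freq` of negative-control
#' AP-MS runs are removed; proteins without a profile are treated as
#' frequency 0 and retained.
#'
#' @param proteins character vector of candidate protein ids.
#' @param profiles tibble with `protein_id`, `contaminant_frequency` in
#'   `[0, 1]`.
#' @param max_freq removal threshold (strict `>`), default 0.20.
#' @return retained protein ids.
#' @export
crapome_filter <- function(proteins, profiles, max_freq = 0.20) {
  stopifnot(is.character(proteins))
  if (!all(c("protein_id", "contaminant_frequency") %in% names(profiles)))
    stop("profiles needs columns protein_id, contaminant_frequency")
  f <- profiles$contaminant_frequency
  if (any(f < 0 | f > 1)) stop("contaminant frequencies must lie in [0, 1]")
  freq <- f[match(proteins, profiles$protein_id)]
  freq[is.na(freq)] <- 0
  proteins[freq <= max_freq]
}

#' Modified spectral-count enrichment statistic
#'
#' The plain pull-down/control ratio is multiplied by the pull-down
#' spectral count, rewarding proteins with abundant bait evidence:
#' `s = (x / (y + c)) * x` with pull-down counts `x`, control counts `y`
#' and control pseudocount `c` (so zero-control ratios are defined).
#'
#' @param bait_counts,control_counts non-negative integer vectors.
#' @param pseudocount control pseudocount `c > 0`, default 1.
#' @return numeric statistic, 0 iff `bait_counts == 0`.
#' @export
enrichment_statistic <- function(bait_counts, control_counts,
                                 pseudocount = 1) {
  stopifnot(pseudocount > 0)
  if (any(bait_counts < 0) || any(control_counts < 0))
    stop("spectral counts must be non-negative")
  (bait_counts / (control_counts + pseudocount)) * bait_counts
}

#' Empirical p-value of a statistic against a within-experiment background
#'
#' `p = #\{s' in background : s' >= s\} / N`. The query protein's own
#' statistic is part of the background, so `p` lies on the grid
#' `\{1/N, ..., 1\}`.
#'
#' @param statistic query value(s).
#' @param background numeric vector of statistics for all scored proteins in
#'   the same experiment (must include the query).
#' @return empirical p-value(s) in `(0, 1]`.
#' @export
empirical_pvalue <- function(statistic, background) {
  if (length(background) == 0) stop("background must be non-empty")
  vapply(statistic, function(s) mean(background >= s), numeric(1))
}

#' Combined cumulative probability of per-experiment p-values
#'
#' With `z` the product of `k` p-values, returns the probability that a
#' product of `k` independent Uniform(0,1) variables falls at or below `z`:
#' `CCP = z * sum_{j=0}^{k-1} (-ln z)^j / j!`, computed via the equivalent
#' upper Gamma(k, 1) tail of `-ln z` for numerical stability. `CCP = z`
#' when `k = 1`; `CCP = 1` when every p is 1.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return combined cumulative probability in `(0, 1]`.
#' @export
combine_ccp <- function(p_values) {
  if (length(p_values) < 1) stop("need at least one p-value")
  if (any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  # -log(prod p) = sum(-log p) is a Gamma(k, 1) draw under the null
  stats::pgamma(sum(-log(p_values)), shape = length(p_values),
                lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = method)
}

#' Call bait interactors from replicated AP-MS spectral counts
#'
#' Runs the full cascade: identification filtering, the detected-in-at-
#' least-`min_experiments` gate, CRAPome-frequency filtering, the modified
#' enrichment statistic and its within-experiment empirical p-value per
#' replicate IP (an experiment where a candidate went undetected
#' contributes p = 1), combination into a CCP score, BH adjustment across
#' surviving proteins, and the FDR call at `fdr_threshold`.
#'
#' @param records spectral-count tibble (see [filter_identifications()]).
#' @param crapome contaminant-frequency tibble or `NULL` to skip.
#' @param experiments character roster of replicate experiment ids; default
#'   the experiments present in `records`.
#' @param fdr_threshold call cutoff on the q-value, default 0.1.
#' @param min_experiments,score_min,peptide_min,crapome_max,pseudocount
#'   cascade thresholds (see the stage functions).
#' @param contaminant_ids known-contaminant ids removed up front.
#' @param adjust_method multiplicity adjustment passed to [bh_fdr()].
#' @return tibble with one row per surviving protein: per-experiment
#'   statistics and p-values (list columns), `n_experiments_detected`,
#'   `product_p`, `ccp`, `q_value`, `called`.
#' @export
call_interactors <- function(records, crapome = NULL, experiments = NULL,
                             fdr_threshold = 0.1, min_experiments = 3,
                             score_min = 10, peptide_min = 2,
                             crapome_max = 0.20, pseudocount = 1,
                             contaminant_ids = character(),
                             adjust_method = "BH") {
  check_spectral_records(records)
  if (is.null(experiments)) experiments <- sort(unique(records$experiment_id))
  if (!all(records$experiment_id %in% experiments))
    stop("records contain experiment ids missing from the declared roster")
  k <- length(experiments)

  kept <- filter_identifications(records, score_min, peptide_min,
                                 contaminant_ids)
  candidates <- detection_filter(kept, min_experiments, total_experiments = k)
  if (!is.null(crapome))
    candidates <- crapome_filter(candidates, crapome, crapome_max)
  if (length(candidates) == 0) {
    return(tibble::tibble(
      protein_id = character(), n_experiments_detected = integer(),
      statistic_per_experiment = list(), empirical_p_per_experiment = list(),
      product_p = numeric(), ccp = numeric(), q_value = numeric(),
      called = logical()
    ))
  }

  scored <- kept |>
    dplyr::filter(.data$protein_id %in% candidates) |>
    dplyr::mutate(statistic = enrichment_statistic(
      .data$bait_counts, .data$control_counts, pseudocount))

  # empirical p against the within-experiment score distribution of all
  # surviving candidates (query included); undetected -> p = 1
  stat_mat <- matrix(NA_real_, nrow = length(candidates), ncol = k,
                     dimnames = list(candidates, experiments))
  stat_mat[cbind(scored$protein_id, scored$experiment_id)] <- scored$statistic
  p_mat <- matrix(1, nrow = length(candidates), ncol = k,
                  dimnames = list(candidates, experiments))
  for (e in experiments) {
    bg <- stat_mat[, e]
    bg <- bg[!is.na(bg)]
    if (length(bg) == 0) next
    idx <- which(!is.na(stat_mat[, e]))
    p_mat[idx, e] <- empirical_pvalue(stat_mat[idx, e], bg)
  }

  ccp <- apply(p_mat, 1, combine_ccp)
  q <- bh_fdr(ccp, method = adjust_method)
  tibble::tibble(
    protein_id = candidates,
    n_experiments_detected = rowSums(!is.na(stat_mat)),
    statistic_per_experiment = lapply(seq_along(candidates),
                                      function(i) stat_mat[i, ]),
    empirical_p_per_experiment = lapply(seq_along(candidates),
                                        function(i) p_mat[i, ]),
    product_p = apply(p_mat, 1, prod),
    ccp = unname(ccp),
    q_value = unname(q),
    called = unname(q <= fdr_threshold)
  )
}

#' Partition two interactor call sets into state-specific and shared sets
#'
#' @param calls_a,calls_b call tables from [call_interactors()] (or
#'   character vectors of called protein ids).
#' @return list with `a_only`, `b_only`, `shared` (sorted character vectors).
#' @export
interactome_overlap <- function(calls_a, calls_b) {
  ids <- function(x) {
    if (is.character(x)) return(unique(x))
    unique(x$protein_id[x$called])
  }
  a <- ids(calls_a); b <- ids(calls_b)
  list(a_only = sort(setdiff(a, b)),
       b_only = sort(setdiff(b, a)),
       shared = sort(intersect(a, b)))
}

check_spectral_records <- function(records) {
  need <- c("protein_id", "experiment_id", "bait_counts", "control_counts",
            "identification_score", "n_peptides")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("spectral-count records missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(records$bait_counts < 0) || any(records$control_counts < 0))
    stop("spectral counts must be non-negative")
  invisible(records)
}
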
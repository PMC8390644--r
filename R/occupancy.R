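#' Build the peaks-by-tracks occupancy matrix over merged peaks
#'
#' For each merged peak and each (factor, state) track, records a binary
#' presence flag using the reciprocal-overlap criterion, and optionally an
#' intensity layer (mean signal per peak) when intensity values are
#' supplied. The intensity layer is what state clustering consumes by
#' default; the binary layer mirrors the overlap table used to define
#' occupancy.
#'
#' @param merged_peaks disjoint GRanges of merged peaks.
#' @param track_peaksets named list of GRanges, one per track (e.g.
#'   `OCT4.naive`, `H3K27ac.primed`).
#' @param track_intensities optional numeric matrix (peaks x tracks) of
#'   mean signal; column names must match `names(track_peaksets)`.
#' @param min_frac reciprocal-overlap fraction, default 0.25.
#' @param either overlap mode, see [reciprocal_overlap()].
#' @return list with `binary` (0/1 matrix), `intensity` (matrix or NULL)
#'   and `peaks` (the input GRanges).
#' @export
build_occupancy_matrix <- function(merged_peaks, track_peaksets,
                                   track_intensities = NULL,
                                   min_frac = 0.25, either = TRUE) {
  if (is.null(names(track_peaksets)) || any(names(track_peaksets) == ""))
    stop("track_peaksets must be a named list")
  n <- length(merged_peaks)
  binary <- matrix(0L, nrow = n, ncol = length(track_peaksets),
                   dimnames = list(NULL, names(track_peaksets)))
  for (tr in names(track_peaksets)) {
    pr <- reciprocal_pairs(merged_peaks, track_peaksets[[tr]],
                           min_frac = min_frac, either = either)
    binary[unique(pr$a), tr] <- 1L
  }
  if (!is.null(track_intensities)) {
    if (!identical(sort(colnames(track_intensities)),
                   sort(names(track_peaksets))))
      stop("intensity columns must match the track roster")
    if (nrow(track_intensities) != n)
      stop("intensity rows must match the merged peaks")
    track_intensities <- track_intensities[, names(track_peaksets),
                                           drop = FALSE]
  }
  list(binary = binary, intensity = track_intensities, peaks = merged_peaks)
}

#' Normalize occupancy tracks to [0, 1] by an upper percentile
#'
#' Each track is divided by its `probs` quantile (default the 95th
#' percentile, bounding the influence of outlier peaks) and truncated at 1.
#'
#' @param mat peaks x tracks matrix.
#' @param probs upper reference quantile, default 0.95.
#' @return normalized matrix on `[0, 1]`.
#' @export
normalize_tracks <- function(mat, probs = 0.95) {
  apply(mat, 2, function(x) {
    q <- stats::quantile(x, probs, names = FALSE)
    if (q <= 0) q <- max(x, 1e-12)
    pmin(x / q, 1)
  })
}

#' Partition an occupancy matrix into chromatin-state clusters by k-means
#'
#' Standard k-means (best of `n_restarts` random starts, Lloyd-style
#' iterations capped at `n_iter_max`), deterministic under `seed`. The
#' published analysis used k = 10 with `iter.max = 1000`, `nstart = 1000`;
#' the defaults here keep those iteration caps with a lighter restart
#' count suited to desk-scale matrices (`n_restarts = 50`), and the
#' faithful value remains one argument away.
#'
#' @param mat numeric matrix, rows = peaks.
#' @param k number of clusters, default 10.
#' @param n_iter_max iteration cap, default 1000.
#' @param n_restarts random restarts, default 50.
#' @param seed RNG seed (required; no global randomness).
#' @return list: `assignments`, `centroids`, `tot_withinss`, `k`, `seed`.
#' @export
kmeans_cluster <- function(mat, k = 10, n_iter_max = 1000, n_restarts = 50,
                           seed) {
  if (missing(seed)) stop("an explicit seed is required")
  mat <- as.matrix(mat)
  if (nrow(mat) < k) stop("fewer rows than clusters")
  if (nrow(unique(mat)) < k)
    stop("fewer distinct rows (", nrow(unique(mat)), ") than clusters")
  fit <- with_seed(seed, stats::kmeans(mat, centers = k,
                                       iter.max = n_iter_max,
                                       nstart = n_restarts))
  list(assignments = fit$cluster, centroids = fit$centers,
       tot_withinss = fit$tot.withinss, k = k, seed = seed,
       n_iter_max = n_iter_max, n_restarts = n_restarts)
}

# track name helpers: tracks are "<mark>.<state>"
track_name <- function(mark, state) paste(mark, state, sep = ".")

#' Annotate k-means chromatin-state clusters from centroid mark patterns
#'
#' Applies a rule table on per-track-normalized centroids (threshold `tau`)
#' over the tracks OCT4, H3K27ac, H3K4me3, H3K27me3 in the two states:
#' \describe{
#'   \item{enhancer}{OCT4 and H3K27ac high, H3K4me3 and H3K27me3 low}
#'   \item{active promoter}{OCT4, H3K27ac and H3K4me3 high, H3K27me3 low}
#'   \item{bivalent promoter}{H3K4me3 and H3K27me3 both high}
#' }
#' A pattern holding in one state only yields a state-specific label
#' (e.g. "naive enhancer"); holding in both yields "shared"; anything
#' else is "other".
#'
#' @param model fit from [kmeans_cluster()].
#' @param tau rule threshold on normalized centroids, default 0.5.
#' @param states the two state suffixes, default `c("naive", "primed")`.
#' @return named character vector: cluster id -> class label.
#' @export
annotate_clusters <- function(model, tau = 0.5,
                              states = c("naive", "primed")) {
  cen <- model$centroids
  marks <- c("OCT4", "H3K27ac", "H3K4me3", "H3K27me3")
  need <- as.vector(outer(marks, states, track_name))
  miss <- setdiff(need, colnames(cen))
  if (length(miss) > 0)
    stop("centroids missing required track(s): ", paste(miss, collapse = ", "))
  # normalize each centroid track by the max across clusters so the rules
  # see relative enrichment regardless of the clustering feature scale
  cen <- apply(cen, 2, function(x) {
    m <- max(x)
    if (m <= 0) x else x / m
  })

  classify_state <- function(row, st) {
    hi <- function(mark) row[track_name(mark, st)] >= tau
    if (hi("H3K4me3") && hi("H3K27me3")) return("bivalent promoter")
    if (hi("OCT4") && hi("H3K27ac")) {
      if (hi("H3K4me3")) return("active promoter") else return("enhancer")
    }
    "none"
  }
  labels <- apply(cen, 1, function(row) {
    c1 <- classify_state(row, states[1])
    c2 <- classify_state(row, states[2])
    if (c1 == c2 && c1 != "none") return(paste("shared", c1))
    if (c1 != "none" && c2 == "none") return(paste(states[1], c1))
    if (c2 != "none" && c1 == "none") return(paste(states[2], c2))
    "other"
  })
  stats::setNames(labels, rownames(model$centroids))
}

#' Cluster sizes and proportions of total peaks
#'
#' @param model fit from [kmeans_cluster()].
#' @param annotation optional labels from [annotate_clusters()].
#' @return tibble: `cluster`, `class` (if annotated), `n_peaks`,
#'   `proportion` (sums to 1).
#' @export
cluster_composition <- function(model, annotation = NULL) {
  tab <- table(model$assignments)
  out <- tibble::tibble(
    cluster = names(tab),
    n_peaks = as.integer(tab),
    proportion = as.integer(tab) / sum(tab)
  )
  if (!is.null(annotation))
    out <- dplyr::mutate(out,
                         class = unname(annotation[out$cluster]),
                         .after = "cluster")
  out
}
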
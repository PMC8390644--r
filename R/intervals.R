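#' @import GenomicRanges
#' @import IRanges
NULL

# Peaks live as GRanges in memory; on disk they are BED, i.e. 0-based
# half-open. bed_to_granges/granges_to_bed do the +-1 shift once.

#' Convert a BED-style data frame (0-based half-open) to GRanges
#'
#' @param df data frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @return GRanges (1-based closed, the Bioconductor convention).
#' @export
bed_to_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start < 0)) stop("BED starts must be non-negative")
  if (any(df$start >= df$end)) stop("intervals must satisfy start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
  if ("name" %in% names(df)) gr$name <- df$name
  if ("score" %in% names(df)) gr$score <- df$score
  gr
}

#' Convert GRanges back to a BED-style tibble (0-based half-open)
#'
#' @param gr GRanges.
#' @return tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
granges_to_bed <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Read a 3-6 column BED file into GRanges
#' @param path BED file path.
#' @return GRanges.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = cols[seq_len(
                            max(utils::count.fields(path, sep = "\t")))])
  df$strand[df$strand %in% "."] <- "*"
  bed_to_granges(df)
}

#' Write GRanges as 6-column BED
#' @param gr GRanges.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  bed <- granges_to_bed(gr)
  bed$strand[bed$strand == "*"] <- "."
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping and book-ended intervals across peak sets
#'
#' Unions one or more peak sets into disjoint regions, the operation used
#' to build merged remodeler (e.g. BRG1 + BAF155) peak sets. Intervals
#' separated by a gap of zero merge, matching default `bedtools merge`
#' semantics; base-pair coverage is preserved and the operation is
#' idempotent.
#'
#' @param ... GRanges objects (or a single list of them).
#' @return merged, sorted GRanges.
#' @export
merge_overlapping <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !methods::is(sets[[1]], "GRanges")) sets <- sets[[1]]
  gr <- do.call(c, lapply(sets, function(g) {
    GenomicRanges::granges(g, use.mcols = FALSE)
  }))
  GenomicRanges::reduce(sort(gr), ignore.strand = TRUE)
}

# qualifying pairs under the reciprocal-overlap criterion; internal kernel
reciprocal_pairs <- function(set_a, set_b, min_frac = 0.25, either = TRUE) {
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must lie in (0, 1]")
  hits <- GenomicRanges::findOverlaps(set_a, set_b, ignore.strand = TRUE)
  if (length(hits) == 0)
    return(tibble::tibble(a = integer(), b = integer()))
  qa <- S4Vectors::queryHits(hits); qb <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(set_a[qa], set_b[qb],
                                  ignore.strand = TRUE)
  l <- GenomicRanges::width(ov)
  fa <- l / GenomicRanges::width(set_a)[qa]
  fb <- l / GenomicRanges::width(set_b)[qb]
  keep <- if (either) (fa >= min_frac | fb >= min_frac)
          else (fa >= min_frac & fb >= min_frac)
  tibble::tibble(a = qa[keep], b = qb[keep])
}

#' Intervals of one set with a reciprocal-overlap partner in another
#'
#' An interval `a` qualifies when some `b` overlaps it by at least
#' `min_frac` of `a`'s length or (with `either = TRUE`, the `-f 0.25
#' -F 0.25 -e` semantics) of `b`'s length; with `either = FALSE` both
#' fractions must reach `min_frac`.
#'
#' @param set_a,set_b merged GRanges (disjoint within each set).
#' @param min_frac minimum covered fraction, default 0.25.
#' @param either one-sided OR (default) vs two-sided AND criterion.
#' @return the qualifying subset of `set_a`.
#' @export
reciprocal_overlap <- function(set_a, set_b, min_frac = 0.25, either = TRUE) {
  pr <- reciprocal_pairs(set_a, set_b, min_frac, either)
  set_a[sort(unique(pr$a))]
}

#' Shared and exclusive peak counts between two merged peak sets
#'
#' The shared count is the number of disjoint regions in the merged union
#' of qualifying intervals from both sets — the single numerator reported
#' against both per-set denominators in two-state peak comparisons.
#' Per-set qualifying counts are returned alongside.
#'
#' @inheritParams reciprocal_overlap
#' @return list: `n_shared` (merged shared regions), `n_a_only`,
#'   `n_b_only`, `n_a_qualifying`, `n_b_qualifying`, `n_a`, `n_b`.
#' @export
shared_peak_count <- function(set_a, set_b, min_frac = 0.25, either = TRUE) {
  pr <- reciprocal_pairs(set_a, set_b, min_frac, either)
  ia <- sort(unique(pr$a)); ib <- sort(unique(pr$b))
  shared <- merge_overlapping(set_a[ia], set_b[ib])
  list(
    n_shared = length(shared),
    n_a_only = length(set_a) - length(ia),
    n_b_only = length(set_b) - length(ib),
    n_a_qualifying = length(ia),
    n_b_qualifying = length(ib),
    n_a = length(set_a),
    n_b = length(set_b)
  )
}

#' Assign peaks to target genes by nearest TSS within a distance cutoff
#'
#' Distance is measured from the peak midpoint `floor((start + end) / 2)`
#' (0-based coordinates) to the TSS position; the nearest gene is assigned
#' when that distance is strictly below `max_dist` (default 20 kb), with
#' ties broken by lexicographically smaller gene id.
#'
#' @param peaks GRanges.
#' @param tss tibble with `gene_id`, `chrom`, `tss_position` (0-based),
#'   `strand`.
#' @param max_dist assignment cutoff in bp (strict `<`), default 20000.
#' @return character vector of gene ids (NA where unassigned), parallel to
#'   `peaks`.
#' @export
assign_target_gene <- function(peaks, tss, max_dist = 20000) {
  stopifnot(all(c("gene_id", "chrom", "tss_position") %in% names(tss)))
  if (nrow(tss) == 0) stop("TSS table must be non-empty")
  mid <- floor((GenomicRanges::start(peaks) - 1 +
                  GenomicRanges::end(peaks)) / 2)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  out <- rep(NA_character_, length(peaks))
  tss <- tss[order(tss$chrom, tss$tss_position, tss$gene_id), ]
  for (ch in unique(chrom)) {
    t_ch <- tss[tss$chrom == ch, ]
    if (nrow(t_ch) == 0) next
    idx <- which(chrom == ch)
    for (i in idx) {
      d <- abs(t_ch$tss_position - mid[i])
      dmin <- min(d)
      if (dmin < max_dist) {
        cand <- t_ch$gene_id[d == dmin]
        out[i] <- min(cand)  # lexicographic tie-break
      }
    }
  }
  out
}

#' One-sided Fisher exact test for overlap enrichment
#'
#' Tests a 2x2 overlap table against the hypergeometric null with
#' alternative "greater" — the convention for asking whether two region
#' sets co-occur more than chance.
#'
#' @param n11,n12,n21,n22 non-negative integer cell counts (row 1 = in
#'   set A, column 1 = in set B).
#' @return p-value in `(0, 1]`.
#' @export
fisher_overlap_test <- function(n11, n12, n21, n22) {
  cells <- c(n11, n12, n21, n22)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE),
                     alternative = "greater")$p.value
}
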
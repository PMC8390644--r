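# Independent brute-force oracles used across the suite. These stay
# deliberately naive (all-pairs scans, hand step-up) so they share no code
# path with the implementation they check.

# Benjamini-Hochberg step-up by the definition q_(i) = min_{j>=i} p_(j)*m/j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin(p[ord][i:m] * m / (i:m), 1))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# random 0-based half-open intervals on a toy chromosome
random_intervals <- function(n, chrom = "c1", max_pos = 1e6,
                             max_width = 5000) {
  start <- sort(sample.int(max_pos - max_width, n))
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width)
}

# sweep-merge of 0-based intervals (book-ended intervals merge)
merge_oracle <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start, d$end), ]
    cur_s <- d$start[1]; cur_e <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= cur_e) {
        cur_e <- max(cur_e, d$end[i])
      } else {
        out[[length(out) + 1]] <- c(ch, cur_s, cur_e)
        cur_s <- d$start[i]; cur_e <- d$end[i]
      }
    }
    out[[length(out) + 1]] <- c(ch, cur_s, cur_e)
  }
  data.frame(chrom = vapply(out, `[`, "", 1),
             start = as.numeric(vapply(out, `[`, "", 2)),
             end = as.numeric(vapply(out, `[`, "", 3)))
}

# all-pairs reciprocal-overlap qualification (0-based half-open input);
# the full n_a x n_b overlap-length matrix is computed, no interval index
reciprocal_oracle <- function(a, b, min_frac = 0.25, either = TRUE) {
  L <- pmin(outer(a$end, b$end, pmin) - outer(a$start, b$start, pmax),
            Inf)
  L[outer(a$chrom, b$chrom, "!=")] <- 0
  L[L < 0] <- 0
  fa <- L / (a$end - a$start)           # recycled down columns
  fb <- sweep(L, 2, b$end - b$start, "/")
  ok <- if (either) (fa >= min_frac | fb >= min_frac) & L > 0
        else (fa >= min_frac & fb >= min_frac) & L > 0
  list(a = apply(ok, 1, any), b = apply(ok, 2, any))
}

# one-sided (greater) Fisher p by summing the hypergeometric tail
fisher_oracle <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12; c1 <- n11 + n21; n <- n11 + n12 + n21 + n22
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  sum(probs[ks >= n11])
}

# all-pairs nearest-TSS assignment with the strict < max_dist rule
nearest_tss_oracle <- function(peaks_bed, tss, max_dist = 20000) {
  vapply(seq_len(nrow(peaks_bed)), function(i) {
    mid <- floor((peaks_bed$start[i] + peaks_bed$end[i]) / 2)
    t_ch <- tss[tss$chrom == peaks_bed$chrom[i], ]
    if (nrow(t_ch) == 0) return(NA_character_)
    d <- abs(t_ch$tss_position - mid)
    if (min(d) >= max_dist) return(NA_character_)
    min(t_ch$gene_id[d == min(d)])
  }, character(1))
}

# majority-vote class recovery of a clustering against planted labels
class_recovery <- function(assignments, truth) {
  tab <- table(assignments, truth)
  sum(apply(tab, 1, max)) / sum(tab)
}
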
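test_that("merge unions overlapping and book-ended intervals and is idempotent", {
  gr <- bed_to_granges(data.frame(chrom = "c1", start = c(100, 150),
                                  end = c(200, 300)))
  m <- merge_overlapping(gr)
  expect_equal(granges_to_bed(m)[, c("start", "end")],
               tibble::tibble(start = 100L, end = 300L))
  # book-ended: [100,200) + [200,300) -> [100,300)
  gr2 <- bed_to_granges(data.frame(chrom = "c1", start = c(100, 200),
                                   end = c(200, 300)))
  expect_equal(nrow(granges_to_bed(merge_overlapping(gr2))), 1)
  # disjoint unchanged; idempotent; coverage preserved
  gr3 <- bed_to_granges(data.frame(chrom = "c1", start = c(0, 20),
                                   end = c(10, 30)))
  m3 <- merge_overlapping(gr3)
  expect_equal(length(m3), 2)
  expect_identical(granges_to_bed(merge_overlapping(m3)),
                   granges_to_bed(m3))
  expect_error(bed_to_granges(data.frame(chrom = "c1", start = 5, end = 5)),
               "start < end")
})

test_that("reciprocal overlap distinguishes either (OR) from both (AND) coverage", {
  a <- bed_to_granges(data.frame(chrom = "c1", start = 100, end = 200))
  b <- bed_to_granges(data.frame(chrom = "c1", start = 150, end = 400))
  # L = 50: 50% of a but 20% of b
  expect_length(reciprocal_overlap(a, b, 0.25, either = TRUE), 1)
  expect_length(reciprocal_overlap(a, b, 0.25, either = FALSE), 0)
  expect_length(reciprocal_overlap(a, a, 0.25, either = FALSE), 1)
  far <- bed_to_granges(data.frame(chrom = "c1", start = 900, end = 950))
  expect_length(reciprocal_overlap(a, far), 0)
  expect_error(reciprocal_overlap(a, b, min_frac = 0), "\\(0, 1\\]")
})

test_that("interval kernel matches the all-pairs brute-force oracle on random sets", {
  set.seed(31)
  for (rep in 1:20) {
    n_a <- sample(50:200, 1); n_b <- sample(50:200, 1)
    a_bed <- random_intervals(n_a)
    b_bed <- random_intervals(n_b)
    a <- merge_overlapping(bed_to_granges(a_bed))
    b <- merge_overlapping(bed_to_granges(b_bed))
    # merged output equals the sweep oracle
    expect_equal(granges_to_bed(a)[, 1:3],
                 tibble::as_tibble(merge_oracle(a_bed)),
                 ignore_attr = TRUE)
    am <- granges_to_bed(a); bm <- granges_to_bed(b)
    for (either in c(TRUE, FALSE)) {
      oracle <- reciprocal_oracle(am, bm, 0.25, either)
      got_a <- reciprocal_overlap(a, b, 0.25, either)
      got_b <- reciprocal_overlap(b, a, 0.25, either)
      expect_equal(length(got_a), sum(oracle$a))
      expect_equal(length(got_b), sum(oracle$b))
      sh <- shared_peak_count(a, b, 0.25, either)
      expect_equal(sh$n_a_qualifying, sum(oracle$a))
      expect_equal(sh$n_b_qualifying, sum(oracle$b))
      expect_equal(sh$n_a_only, nrow(am) - sum(oracle$a))
      # shared regions equal the sweep-merged union of qualifying intervals
      qual <- rbind(am[oracle$a, 1:3], bm[oracle$b, 1:3])
      exp_shared <- if (nrow(qual) == 0) 0 else nrow(merge_oracle(qual))
      expect_equal(sh$n_shared, exp_shared)
    }
  }
})

test_that("overlap symmetry: a pairs with b iff b pairs with a under either mode", {
  set.seed(12)
  a <- merge_overlapping(bed_to_granges(random_intervals(100)))
  b <- merge_overlapping(bed_to_granges(random_intervals(100)))
  sab <- shared_peak_count(a, b)
  sba <- shared_peak_count(b, a)
  expect_equal(sab$n_shared, sba$n_shared)
  expect_equal(sab$n_a_qualifying, sba$n_b_qualifying)
})

test_that("identical and disjoint sets give the degenerate shared counts", {
  a <- merge_overlapping(bed_to_granges(random_intervals(50)))
  self <- shared_peak_count(a, a)
  expect_equal(self$n_shared, length(a))
  expect_equal(self$n_a_only, 0)
  b <- GenomicRanges::shift(a, 2e6)
  none <- shared_peak_count(a, b)
  expect_equal(none$n_shared, 0)
  expect_equal(none$n_a_only, length(a))
})

test_that("printed-ratio arithmetic: percentages round half-up and unions add up", {
  expect_equal(overlap_fraction(26428, 49846), 53.0)
  expect_equal(overlap_fraction(15463, 17413), 88.8)
  expect_equal(overlap_fraction(0, 10), 0)
  expect_equal(overlap_fraction(1, 8), 12.5)  # exact half stays .5
  expect_equal(round_half_up(0.25, 1), 0.3)   # half rounds up, not to even
  expect_error(overlap_fraction(1, 0), "> 0")
  expect_equal(union_count(49846, 45589, 26428), 69007)
  expect_equal(union_count(10, 10, 10), 10)
  expect_equal(union_count(10, 5, 0), 15)
  expect_error(union_count(1, 1, 5), "inconsistent")
})

test_that("nearest-TSS assignment honors the strict 20 kb rule and tie-break", {
  tss <- tibble::tibble(gene_id = c("G2", "G1", "G3"),
                        chrom = c("c1", "c1", "c2"),
                        tss_position = c(21499, 6500, 100),
                        strand = c("+", "-", "+"))
  pk <- bed_to_granges(data.frame(chrom = "c1", start = 1000, end = 2000))
  # midpoint 1500: G1 at 5000, G2 at 19999 -> nearest G1
  expect_equal(assign_target_gene(pk, tss), "G1")
  # G2 exactly 19,999 away is assignable; 20,000 is not
  expect_equal(assign_target_gene(pk, tss[1, ]), "G2")
  tss20 <- tibble::tibble(gene_id = "G9", chrom = "c1",
                          tss_position = 21500, strand = "+")
  expect_true(is.na(assign_target_gene(pk, tss20)))
  # equidistant genes resolve to the lexicographically smaller id
  tie <- tibble::tibble(gene_id = c("GB", "GA"), chrom = "c1",
                        tss_position = c(1400, 1600), strand = "+")
  expect_equal(assign_target_gene(pk, tie), "GA")
  # chromosome absent from the annotation -> unassigned
  pk2 <- bed_to_granges(data.frame(chrom = "c9", start = 0, end = 10))
  expect_true(is.na(assign_target_gene(pk2, tss)))
  expect_error(assign_target_gene(pk, tss[0, ]), "non-empty")
})

test_that("nearest-TSS assignment matches the all-pairs oracle on random inputs", {
  set.seed(77)
  for (rep in 1:10) {
    bed <- random_intervals(80, max_pos = 5e5)
    tss <- tibble::tibble(
      gene_id = sprintf("G%03d", sample(999, 60)),
      chrom = sample(c("c1", "c2"), 60, replace = TRUE),
      tss_position = sample.int(5e5, 60), strand = "+")
    got <- assign_target_gene(bed_to_granges(bed), tss)
    expect_equal(got, nearest_tss_oracle(bed, tss))
  }
})

test_that("one-sided Fisher overlap test equals the hypergeometric tail", {
  expect_equal(fisher_overlap_test(10, 0, 0, 10), 1 / choose(20, 10))
  expect_equal(fisher_overlap_test(5, 5, 5, 5), fisher_oracle(5, 5, 5, 5))
  expect_equal(fisher_overlap_test(0, 5, 5, 5), 1)
  set.seed(3)
  for (i in 1:25) {
    cells <- sample(0:30, 4, replace = TRUE)
    expect_equal(fisher_overlap_test(cells[1], cells[2], cells[3], cells[4]),
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]))
  }
  expect_error(fisher_overlap_test(-1, 1, 1, 1), "non-negative")
})

test_that("BED round-trips through files preserve coordinates", {
  bed <- random_intervals(20)
  gr <- bed_to_granges(bed)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, path)
  back <- read_bed(path)
  expect_equal(granges_to_bed(back)[, 1:3],
               granges_to_bed(gr)[, 1:3])
})
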
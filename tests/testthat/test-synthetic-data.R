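test_that("generators are pure functions of their config, seed included", {
  cfg <- apms_sim_config(n_proteins = 150, n_true_interactors = 10, seed = 4)
  expect_identical(simulate_apms(cfg), simulate_apms(cfg))
  expect_identical(simulate_crapome(cfg), simulate_crapome(cfg))
  g <- genome_sim_config(seed = 4)
  l1 <- simulate_peak_landscape(g); l2 <- simulate_peak_landscape(g)
  expect_identical(l1$truth, l2$truth)
  expect_identical(l1$intensity, l2$intensity)
  e <- expr_sim_config(n_genes = 200, seed = 4)
  expect_identical(simulate_expression(e), simulate_expression(e))
  a <- atac_sim_config(n_peaks = 200, seed = 4)
  expect_identical(simulate_atac_counts(a), simulate_atac_counts(a))
  # generators do not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_apms(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("config validation rejects impossible study designs", {
  expect_error(apms_sim_config(n_proteins = 5, n_true_interactors = 10),
               "exceed")
  expect_error(apms_sim_config(dropout_rate = 1), "dropout")
  expect_error(apms_sim_config(enrichment_fold = 0.5), "enrichment_fold")
  expect_error(genome_sim_config(mark_signal = 1, mark_noise = 2),
               "exceed")
  expect_error(genome_sim_config(
    n_peaks_per_class = c(naive_enhancer = 1)), "classes")
  expect_error(expr_sim_config(n_genes = 10, n_deg_up = 8, n_deg_down = 8),
               "exceed")
  expect_error(expr_sim_config(n_replicates = 1), "replicates")
  expect_error(atac_sim_config(n_replicates = 1), "replicates")
  # peaks must fit on the pseudo-genome
  tiny <- genome_sim_config(chrom_sizes = c(chrS1 = 30000))
  expect_error(simulate_peak_landscape(tiny), "chromosome sizes")
})

test_that("true preys are detected in every experiment when dropout is zero", {
  cfg <- apms_sim_config(n_proteins = 100, n_true_interactors = 20,
                         dropout_rate = 0, seed = 2)
  sim <- simulate_apms(cfg)
  preys <- sim$truth$protein_id[sim$truth$is_true_interactor]
  n_seen <- table(sim$records$protein_id[sim$records$protein_id %in% preys])
  expect_true(all(n_seen == cfg$n_experiments))
})

test_that("planted preys are enriched over a matched background", {
  cfg <- apms_sim_config(n_proteins = 1000, n_true_interactors = 50,
                         enrichment_fold = 10, dropout_rate = 0, seed = 8)
  sim <- simulate_apms(cfg)
  prey <- sim$records$protein_id %in%
    sim$truth$protein_id[sim$truth$is_true_interactor]
  ratio <- mean(sim$records$bait_counts[prey]) /
    mean(sim$records$bait_counts[!prey])
  expect_gt(ratio, 0.7 * cfg$enrichment_fold)
  expect_lt(ratio, 1.3 * cfg$enrichment_fold)
  # contaminants have matched bait/control means
  expect_lt(abs(mean(sim$records$bait_counts[!prey]) -
                  mean(sim$records$control_counts[!prey])),
            0.1 * cfg$background_mean)
})

test_that("null simulations give uniform empirical p-values", {
  cfg <- apms_sim_config(n_proteins = 2000, n_true_interactors = 0,
                         enrichment_fold = 1, seed = 6)
  sim <- simulate_apms(cfg)
  crap <- simulate_crapome(cfg, sim$truth)
  calls <- call_interactors(sim$records, crap,
                            experiments = sim$experiments)
  stat <- vapply(calls$statistic_per_experiment, `[[`, numeric(1), "IP1")
  p1 <- vapply(calls$empirical_p_per_experiment, `[[`,
               numeric(1), "IP1")[!is.na(stat)]
  expect_gt(suppressWarnings(stats::ks.test(p1, "punif"))$p.value, 0.01)
  # chi-square goodness of fit on deciles
  obs <- table(cut(p1, seq(0, 1, 0.1)))
  expect_gt(suppressWarnings(stats::chisq.test(obs))$p.value, 0.01)
})

test_that("contaminant-frequency table separates sticky contaminants from preys", {
  cfg <- apms_sim_config(n_proteins = 400, n_true_interactors = 30,
                         n_sticky = 50, crapome_runs = 100, seed = 3)
  sim <- simulate_apms(cfg)
  crap <- simulate_crapome(cfg, sim$truth)
  expect_true(all(crap$contaminant_frequency >= 0 &
                    crap$contaminant_frequency <= 1))
  expect_equal(crap$contaminant_frequency,
               crap$n_runs_detected / cfg$crapome_runs)
  sticky <- sim$truth$is_sticky[match(crap$protein_id,
                                      sim$truth$protein_id)]
  prey <- sim$truth$is_true_interactor[match(crap$protein_id,
                                             sim$truth$protein_id)]
  expect_true(all(crap$contaminant_frequency[sticky] > 0.2))
  expect_true(all(crap$contaminant_frequency[prey] <= 0.2))
})

test_that("planted landscape classes carry the annotation-rule mark patterns", {
  land <- simulate_peak_landscape(genome_sim_config(seed = 10))
  biv <- land$truth$class == "bivalent_promoter"
  # bivalent promoters: high H3K4me3 and H3K27me3, low H3K27ac
  expect_gt(mean(land$intensity[biv, "H3K4me3.naive"]), 5)
  expect_gt(mean(land$intensity[biv, "H3K27me3.primed"]), 5)
  expect_lt(mean(land$intensity[biv, "H3K27ac.naive"]), 2)
  ne <- land$truth$class == "naive_enhancer"
  expect_gt(mean(land$intensity[ne, "OCT4.naive"]), 5)
  expect_lt(mean(land$intensity[ne, "OCT4.primed"]), 2)
  expect_lt(mean(land$intensity[ne, "H3K4me3.naive"]), 2)
  # peaks are disjoint and within chromosome bounds
  expect_equal(length(merge_overlapping(land$peaks)), length(land$peaks))
  bed <- granges_to_bed(land$peaks)
  cfg <- genome_sim_config()
  expect_true(all(bed$end <= cfg$chrom_sizes[bed$chrom]))
})

test_that("a fraction of class peaks lies within 20 kb of a planted TSS", {
  cfg <- genome_sim_config(seed = 14, frac_near_tss = 0.7)
  land <- simulate_peak_landscape(cfg)
  assigned <- assign_target_gene(land$peaks, land$tss)
  cls <- land$truth$class != "background"
  expect_gt(mean(!is.na(assigned[cls])), 0.6)
})

test_that("a structureless landscape yields no annotated enhancer class", {
  counts <- stats::setNames(c(0, 0, 0, 0, 0, 300),
                            c("naive_enhancer", "primed_enhancer",
                              "shared_enhancer", "active_promoter",
                              "bivalent_promoter", "background"))
  land <- simulate_peak_landscape(genome_sim_config(
    n_peaks_per_class = counts, n_genes = 100, seed = 21))
  occ <- build_occupancy_matrix(land$peaks, land$track_peaks,
                                land$intensity)
  km <- kmeans_cluster(normalize_tracks(occ$intensity), k = 3, seed = 1)
  ann <- annotate_clusters(km)
  expect_false(any(grepl("enhancer", ann)))
})

test_that("expression and ATAC simulators plant the advertised effect sizes", {
  e <- simulate_expression(expr_sim_config(n_genes = 2000, n_deg_up = 60,
                                           n_deg_down = 60, seed = 5))
  lf <- log2(rowMeans(e$matrix[, e$groups$B]) /
               rowMeans(e$matrix[, e$groups$A]))
  expect_gt(mean(lf[e$truth$deg == "up"]), 2.5)
  expect_lt(mean(lf[e$truth$deg == "down"]), -2.5)
  expect_lt(abs(mean(lf[e$truth$deg == "null"])), 0.1)
  a <- simulate_atac_counts(atac_sim_config(n_peaks = 2000, seed = 5))
  lfa <- log2((1 + rowMeans(a$counts[, a$groups$KO])) /
                (1 + rowMeans(a$counts[, a$groups$WT])))
  expect_lt(mean(lfa[a$truth$dar == "down"]), -2)
})
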
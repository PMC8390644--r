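# Synthetic-data generators. Every generator is a pure function of its
# config (seed included): identical configs give identical outputs, and
# truth labels are emitted alongside each dataset so downstream stages
# carry recovery tests.

nb_draw <- function(n, mu, dispersion) {
  # negative binomial with mean mu and dispersion phi (var = mu + phi mu^2);
  # phi -> 0 degenerates to Poisson
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Configuration for the AP-MS spectral-count simulator
#'
#' @param n_proteins total proteins observed across the study.
#' @param n_true_interactors planted bait-specific preys.
#' @param n_experiments replicate IP experiments, default 4.
#' @param enrichment_fold mean bait/control count ratio for true preys
#'   (must exceed 1 except for null simulations where 1 is allowed).
#' @param background_mean mean spectral count for background proteins.
#' @param dispersion negative-binomial dispersion of counts
#'   (variance `mu + phi mu^2`); 0 gives Poisson.
#' @param dropout_rate probability a true prey goes undetected in one
#'   experiment.
#' @param id_fail_rate fraction of records failing the identification
#'   gate (score > 10 and peptides > 2).
#' @param n_sticky background proteins designated frequent contaminants
#'   (CRAPome frequency > 20%); default 5% of the background.
#' @param crapome_runs number of emulated negative-control runs.
#' @param seed RNG seed.
#' @return validated `apms_sim_config` list.
#' @export
apms_sim_config <- function(n_proteins = 2000, n_true_interactors = 30,
                            n_experiments = 4, enrichment_fold = 10,
                            background_mean = 20, dispersion = 0.1,
                            dropout_rate = 0.1, id_fail_rate = 0.05,
                            n_sticky = NULL, crapome_runs = 400, seed = 1) {
  if (is.null(n_sticky))
    n_sticky <- floor(0.05 * (n_proteins - n_true_interactors))
  cfg <- list(n_proteins = n_proteins,
              n_true_interactors = n_true_interactors,
              n_experiments = n_experiments,
              enrichment_fold = enrichment_fold,
              background_mean = background_mean, dispersion = dispersion,
              dropout_rate = dropout_rate, id_fail_rate = id_fail_rate,
              n_sticky = n_sticky, crapome_runs = crapome_runs, seed = seed)
  with(cfg, {
    if (n_true_interactors > n_proteins)
      stop("n_true_interactors cannot exceed n_proteins")
    if (enrichment_fold < 1)
      stop("enrichment_fold must be >= 1")
    if (dropout_rate < 0 || dropout_rate >= 1)
      stop("dropout_rate must lie in [0, 1)")
    if (n_sticky > n_proteins - n_true_interactors)
      stop("n_sticky cannot exceed the background protein count")
    if (crapome_runs < 1) stop("crapome_runs must be >= 1")
    if (background_mean <= 0) stop("background_mean must be positive")
  })
  structure(cfg, class = "apms_sim_config")
}

#' Simulate replicated AP-MS spectral-count tables with planted preys
#'
#' True interactors carry bait counts with mean
#' `enrichment_fold * background_mean` against a matched background;
#' contaminants have equal bait and control means. Identification scores
#' and peptide counts are drawn so that `id_fail_rate` of records fail the
#' score/peptide gate, and each true-prey record drops out of an
#' experiment with probability `dropout_rate`.
#'
#' @param config an [apms_sim_config()].
#' @return list: `records` (tibble: `protein_id`, `experiment_id`,
#'   `bait_counts`, `control_counts`, `identification_score`,
#'   `n_peptides`), `truth` (tibble: `protein_id`,
#'   `is_true_interactor`, `is_sticky`), `experiments` (roster).
#' @export
simulate_apms <- function(config) {
  stopifnot(inherits(config, "apms_sim_config"))
  with_seed(config$seed, {
    n <- config$n_proteins
    ids <- sprintf("P%05d", seq_len(n))
    is_true <- seq_len(n) <= config$n_true_interactors
    is_sticky <- !is_true &
      seq_len(n) <= config$n_true_interactors + config$n_sticky
    experiments <- sprintf("IP%d", seq_len(config$n_experiments))

    grid <- expand.grid(protein_id = ids, experiment_id = experiments,
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$protein_id, grid$experiment_id), ]
    prey <- grid$protein_id %in% ids[is_true]
    mu_bait <- ifelse(prey, config$enrichment_fold * config$background_mean,
                      config$background_mean)
    m <- nrow(grid)
    bait <- nb_draw(m, mu_bait, config$dispersion)
    ctrl <- nb_draw(m, config$background_mean, config$dispersion)

    fail <- stats::runif(m) < config$id_fail_rate
    score <- ifelse(fail, stats::runif(m, 0, 10),
                    10 + stats::rexp(m, rate = 1 / 15))
    # half of the failing records fail on peptides instead of score
    fail_pept <- fail & stats::runif(m) < 0.5
    score[fail_pept] <- 10 + stats::rexp(sum(fail_pept), rate = 1 / 15)
    pept <- 3 + stats::rpois(m, 4)
    pept[fail_pept] <- sample(0:2, sum(fail_pept), replace = TRUE)

    drop <- prey & stats::runif(m) < config$dropout_rate
    records <- tibble::tibble(
      protein_id = grid$protein_id,
      experiment_id = grid$experiment_id,
      bait_counts = as.integer(bait),
      control_counts = as.integer(ctrl),
      identification_score = score,
      n_peptides = as.integer(pept)
    )[!drop, ]

    list(records = records,
         truth = tibble::tibble(protein_id = ids,
                                is_true_interactor = is_true,
                                is_sticky = is_sticky),
         experiments = experiments)
  })
}

#' Simulate a CRAPome-style contaminant-frequency table
#'
#' Sticky contaminants (per the truth labels of [simulate_apms()]) appear
#' in strictly more than 20% of the emulated negative-control runs; all
#' other proteins, true preys included, appear in at most 20%.
#'
#' @param config an [apms_sim_config()].
#' @param truth truth tibble from [simulate_apms()] (regenerated from the
#'   config when omitted).
#' @return tibble: `protein_id`, `n_runs_detected`,
#'   `contaminant_frequency`.
#' @export
simulate_crapome <- function(config, truth = NULL) {
  stopifnot(inherits(config, "apms_sim_config"))
  if (is.null(truth)) truth <- simulate_apms(config)$truth
  with_seed(config$seed + 1L, {
    runs <- config$crapome_runs
    cut <- floor(0.2 * runs)          # largest count with frequency <= 0.2
    n <- nrow(truth)
    lo <- sample.int(cut + 1, n, replace = TRUE) - 1L      # 0..cut
    hi <- cut + sample.int(runs - cut, n, replace = TRUE)  # cut+1..runs
    detected <- ifelse(truth$is_sticky, hi, lo)
    tibble::tibble(
      protein_id = truth$protein_id,
      n_runs_detected = as.integer(detected),
      contaminant_frequency = detected / runs
    )
  })
}

peak_classes <- c("naive_enhancer", "primed_enhancer", "shared_enhancer",
                  "active_promoter", "bivalent_promoter", "background")

# planted mark patterns per class: which tracks are "on"
class_pattern_table <- function(states = c("naive", "primed")) {
  marks <- c("OCT4", "H3K27ac", "H3K4me3", "H3K27me3")
  tracks <- as.vector(outer(marks, states, track_name))
  pat <- matrix(0L, nrow = length(peak_classes), ncol = length(tracks),
                dimnames = list(peak_classes, tracks))
  on <- function(class, mark, st) {
    pat[class, track_name(mark, st)] <<- 1L
  }
  on("naive_enhancer", "OCT4", "naive"); on("naive_enhancer", "H3K27ac", "naive")
  on("primed_enhancer", "OCT4", "primed"); on("primed_enhancer", "H3K27ac", "primed")
  for (st in states) {
    on("shared_enhancer", "OCT4", st); on("shared_enhancer", "H3K27ac", st)
    on("active_promoter", "OCT4", st); on("active_promoter", "H3K27ac", st)
    on("active_promoter", "H3K4me3", st)
    on("bivalent_promoter", "H3K4me3", st); on("bivalent_promoter", "H3K27me3", st)
  }
  pat
}

#' Configuration for the planted chromatin-state peak landscape
#'
#' @param n_peaks_per_class named counts for the six planted classes
#'   (`naive_enhancer`, `primed_enhancer`, `shared_enhancer`,
#'   `active_promoter`, `bivalent_promoter`, `background`).
#' @param chrom_sizes named chromosome lengths of the pseudo-genome.
#' @param mark_signal mean intensity where a mark is planted "on".
#' @param mark_noise mean intensity where it is "off" (signal/noise is
#'   their ratio).
#' @param mark_cv coefficient of variation of per-peak mean intensities
#'   around the class means (default 0.25, typical of signal averaged
#'   over a few hundred bp).
#' @param n_genes genes in the TSS annotation.
#' @param frac_near_tss fraction of non-background peaks planted within
#'   20 kb of a TSS.
#' @param peak_width_meanlog,peak_width_sdlog log-normal peak widths
#'   (default median 500 bp).
#' @param seed RNG seed.
#' @return validated `genome_sim_config` list.
#' @export
genome_sim_config <- function(n_peaks_per_class = stats::setNames(
                                c(600, 600, 600, 500, 400, 800),
                                peak_classes),
                              chrom_sizes = c(chrS1 = 12e6, chrS2 = 10e6,
                                              chrS3 = 8e6),
                              mark_signal = 10, mark_noise = 1,
                              mark_cv = 0.25,
                              n_genes = 1500, frac_near_tss = 0.7,
                              peak_width_meanlog = log(500),
                              peak_width_sdlog = 0.25, seed = 1) {
  if (!setequal(names(n_peaks_per_class), peak_classes))
    stop("n_peaks_per_class must name exactly the classes: ",
         paste(peak_classes, collapse = ", "))
  if (mark_signal <= mark_noise)
    stop("mark_signal must exceed mark_noise")
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  if (mark_cv <= 0) stop("mark_cv must be positive")
  structure(list(n_peaks_per_class = n_peaks_per_class[peak_classes],
                 chrom_sizes = chrom_sizes, mark_signal = mark_signal,
                 mark_noise = mark_noise, mark_cv = mark_cv,
                 n_genes = n_genes,
                 frac_near_tss = frac_near_tss,
                 peak_width_meanlog = peak_width_meanlog,
                 peak_width_sdlog = peak_width_sdlog, seed = seed),
            class = "genome_sim_config")
}

#' Simulate a peak landscape with planted chromatin-state classes
#'
#' Places disjoint peaks on a pseudo-genome, assigns each a planted class
#' whose mark pattern follows the annotation rules (e.g. bivalent
#' promoters carry high H3K4me3 and H3K27me3, enhancers carry OCT4 and
#' H3K27ac without H3K4me3), draws per-track intensities around
#' `mark_signal`/`mark_noise`, derives per-track peak sets from the "on"
#' peaks, and plants TSSs within 20 kb of a configurable fraction of
#' non-background peaks.
#'
#' @param config a [genome_sim_config()].
#' @return list: `peaks` (GRanges, one per planted peak), `truth`
#'   (tibble: `peak_id`, `class`), `intensity` (peaks x tracks matrix),
#'   `track_peaks` (named list of GRanges), `tss` (tibble: `gene_id`,
#'   `chrom`, `tss_position`, `strand`).
#' @export
simulate_peak_landscape <- function(config) {
  stopifnot(inherits(config, "genome_sim_config"))
  with_seed(config$seed, {
    n_total <- sum(config$n_peaks_per_class)
    # disjoint placement: one peak per 3 kb slot, slots sampled genome-wide
    slot <- 3000
    n_slots <- floor(config$chrom_sizes / slot)
    if (n_total > sum(n_slots))
      stop("too many peaks for the configured chromosome sizes")
    slot_chrom <- rep(names(n_slots), n_slots)
    slot_idx <- unlist(lapply(n_slots, seq_len), use.names = FALSE)
    pick <- sort(sample.int(sum(n_slots), n_total))
    width <- pmin(round(stats::rlnorm(n_total, config$peak_width_meanlog,
                                      config$peak_width_sdlog)), slot - 10)
    width <- pmax(width, 50)
    offset <- floor(stats::runif(n_total) * (slot - width))
    start0 <- (slot_idx[pick] - 1) * slot + offset
    chrom <- slot_chrom[pick]

    class <- sample(rep(peak_classes, config$n_peaks_per_class))
    peak_id <- sprintf("peak%05d", seq_len(n_total))
    peaks <- bed_to_granges(tibble::tibble(
      chrom = chrom, start = start0, end = start0 + width, name = peak_id))

    pat <- class_pattern_table()
    on <- pat[class, , drop = FALSE]  # peaks x tracks 0/1
    # gamma intensities around the on/off means (shape = 1 / CV^2)
    mu <- ifelse(on == 1, config$mark_signal, config$mark_noise)
    shape <- 1 / config$mark_cv^2
    intensity <- matrix(stats::rgamma(length(mu), shape = shape,
                                      scale = mu / shape),
                        nrow = n_total, dimnames = dimnames(on))
    rownames(intensity) <- peak_id

    track_peaks <- lapply(colnames(on), function(tr) {
      peaks[on[, tr] == 1]
    })
    names(track_peaks) <- colnames(on)

    # TSS annotation: a planted TSS near a fraction of class peaks, plus
    # random extra genes up to n_genes
    near <- which(class != "background" &
                    stats::runif(n_total) < config$frac_near_tss)
    mid <- floor((start0 + start0 + width) / 2)
    tss_pos <- pmax(mid[near] +
                      round(stats::runif(length(near), -15000, 15000)), 0)
    tss <- tibble::tibble(chrom = chrom[near], tss_position = tss_pos)
    n_extra <- max(config$n_genes - nrow(tss), 0)
    if (n_extra > 0) {
      ch <- sample(names(config$chrom_sizes), n_extra, replace = TRUE)
      tss <- dplyr::bind_rows(tss, tibble::tibble(
        chrom = ch,
        tss_position = floor(stats::runif(n_extra) * config$chrom_sizes[ch])
      ))
    }
    tss <- tss[order(tss$chrom, tss$tss_position), ]
    tss$gene_id <- sprintf("G%05d", seq_len(nrow(tss)))
    tss$strand <- sample(c("+", "-"), nrow(tss), replace = TRUE)

    list(peaks = peaks,
         truth = tibble::tibble(peak_id = peak_id, class = class),
         intensity = intensity, track_peaks = track_peaks,
         tss = tss[, c("gene_id", "chrom", "tss_position", "strand")])
  })
}

#' Configuration for the two-condition expression simulator
#'
#' @param n_genes total genes.
#' @param n_replicates replicates per condition, default 2.
#' @param n_deg_up,n_deg_down planted DEGs up/down in condition B.
#' @param effect_log2fc planted absolute log2 fold change.
#' @param dispersion standard deviation of log2 expression noise.
#' @param base_meanlog2,base_sdlog2 baseline log2 FPKM distribution.
#' @param seed RNG seed.
#' @return validated `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_genes = 5000, n_replicates = 2,
                            n_deg_up = 100, n_deg_down = 100,
                            effect_log2fc = 3, dispersion = 0.2,
                            base_meanlog2 = 4, base_sdlog2 = 1.5,
                            seed = 1) {
  if (n_deg_up + n_deg_down > n_genes)
    stop("planted DEGs cannot exceed n_genes")
  if (n_replicates < 2) stop("need at least 2 replicates (t-test undefined)")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(n_genes = n_genes, n_replicates = n_replicates,
                 n_deg_up = n_deg_up, n_deg_down = n_deg_down,
                 effect_log2fc = effect_log2fc, dispersion = dispersion,
                 base_meanlog2 = base_meanlog2, base_sdlog2 = base_sdlog2,
                 seed = seed),
            class = "expr_sim_config")
}

#' Simulate a two-condition expression matrix with planted DEGs
#'
#' Baseline expression is log-normal; planted DEGs shift condition B by
#' `+/- effect_log2fc` on the log2 scale, nulls carry no shift; per-sample
#' noise is log-normal with standard deviation `dispersion` (log2 scale).
#'
#' @param config an [expr_sim_config()].
#' @return list: `matrix` (FPKM-scale genes x samples, columns
#'   `A_rep1..`, `B_rep1..`), `truth` (tibble: `gene_id`, `deg`
#'   in `up`/`down`/`null`), `groups` (list of column names per
#'   condition).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes; r <- config$n_replicates
    gene_id <- sprintf("G%05d", seq_len(n))
    deg <- rep("null", n)
    deg[seq_len(config$n_deg_up)] <- "up"
    deg[config$n_deg_up + seq_len(config$n_deg_down)] <- "down"
    deg <- sample(deg)
    base <- stats::rnorm(n, config$base_meanlog2, config$base_sdlog2)
    # keep planted effects on well-expressed genes so the fold change is
    # not flattened by the pseudocount
    base[deg != "null"] <- pmax(base[deg != "null"], 3)
    shift <- ifelse(deg == "up", config$effect_log2fc,
                    ifelse(deg == "down", -config$effect_log2fc, 0))
    mu <- cbind(matrix(base, n, r), matrix(base + shift, n, r))
    noise <- matrix(stats::rnorm(n * 2 * r, 0, config$dispersion), n)
    values <- 2^(mu + noise)
    colnames(values) <- c(sprintf("A_rep%d", seq_len(r)),
                          sprintf("B_rep%d", seq_len(r)))
    rownames(values) <- gene_id
    list(matrix = values,
         truth = tibble::tibble(gene_id = gene_id, deg = deg),
         groups = list(A = colnames(values)[seq_len(r)],
                       B = colnames(values)[r + seq_len(r)]))
  })
}

#' Configuration for the per-peak ATAC count simulator
#'
#' @param n_peaks total peaks.
#' @param n_replicates replicates per group, default 3.
#' @param n_dar_down,n_dar_up planted accessibility losses/gains in the
#'   knockout group.
#' @param effect_log2fc planted absolute log2 fold change (3 = 8-fold).
#' @param dispersion negative-binomial dispersion.
#' @param base_mean mean read count per peak.
#' @param seed RNG seed.
#' @return validated `atac_sim_config` list.
#' @export
atac_sim_config <- function(n_peaks = 5000, n_replicates = 3,
                            n_dar_down = 200, n_dar_up = 0,
                            effect_log2fc = 3, dispersion = 0.1,
                            base_mean = 100, seed = 1) {
  if (n_dar_down + n_dar_up > n_peaks)
    stop("planted DARs cannot exceed n_peaks")
  if (n_replicates < 2) stop("need at least 2 replicates (t-test undefined)")
  structure(list(n_peaks = n_peaks, n_replicates = n_replicates,
                 n_dar_down = n_dar_down, n_dar_up = n_dar_up,
                 effect_log2fc = effect_log2fc, dispersion = dispersion,
                 base_mean = base_mean, seed = seed),
            class = "atac_sim_config")
}

#' Simulate a per-peak ATAC count matrix with planted accessibility changes
#'
#' Counts are negative binomial around a per-peak baseline; planted DARs
#' scale the knockout-group mean by `2^(+/- effect_log2fc)`.
#'
#' @param config an [atac_sim_config()].
#' @param peak_ids optional peak identifiers (e.g. from a simulated
#'   landscape) of length `n_peaks`.
#' @param dar_labels optional planted labels (`"down"`/`"up"`/`"null"`,
#'   length `n_peaks`), e.g. to place accessibility loss at specific
#'   landscape classes; defaults to a random placement respecting
#'   `n_dar_down`/`n_dar_up`.
#' @return list: `counts` (peaks x samples, columns `WT_rep1..`,
#'   `KO_rep1..`), `truth` (tibble: `peak_id`, `dar` in
#'   `up`/`down`/`null`), `groups`.
#' @export
simulate_atac_counts <- function(config, peak_ids = NULL,
                                 dar_labels = NULL) {
  stopifnot(inherits(config, "atac_sim_config"))
  with_seed(config$seed, {
    n <- config$n_peaks; r <- config$n_replicates
    if (is.null(peak_ids)) peak_ids <- sprintf("peak%05d", seq_len(n))
    if (length(peak_ids) != n) stop("peak_ids must have length n_peaks")
    if (is.null(dar_labels)) {
      dar <- rep("null", n)
      dar[seq_len(config$n_dar_down)] <- "down"
      dar[config$n_dar_down + seq_len(config$n_dar_up)] <- "up"
      dar <- sample(dar)
    } else {
      if (length(dar_labels) != n ||
            !all(dar_labels %in% c("down", "up", "null")))
        stop("dar_labels must be down/up/null of length n_peaks")
      dar <- dar_labels
    }
    base <- config$base_mean * stats::rlnorm(n, 0, 0.5)
    mult <- ifelse(dar == "down", 2^(-config$effect_log2fc),
                   ifelse(dar == "up", 2^config$effect_log2fc, 1))
    mu <- cbind(matrix(base, n, r), matrix(base * mult, n, r))
    counts <- matrix(nb_draw(length(mu), as.vector(mu), config$dispersion),
                     nrow = n)
    colnames(counts) <- c(sprintf("WT_rep%d", seq_len(r)),
                          sprintf("KO_rep%d", seq_len(r)))
    rownames(counts) <- peak_ids
    list(counts = counts,
         truth = tibble::tibble(peak_id = peak_ids, dar = dar),
         groups = list(WT = colnames(counts)[seq_len(r)],
                       KO = colnames(counts)[r + seq_len(r)]))
  })
}
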
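#' Synthetic-dataset configuration
#'
#' Bundles every parameter of the synthetic contact-map generator: a
#' desk-scale genome, an RNA roster with log-normal expression, the
#' distance-decay kernel and per-bin DNA bias of the generative model,
#' the beta-binomial trans-contact null (chromosome intercepts,
#' log-expression coefficient, overdispersion), planted effects
#' (trans/cis delocalization offsets in logit units, an XIST-like RNA
#' that spreads in cis while being excluded from trans chromosomes,
#' distal peak RNAs), two-state expression dynamics, and per-gene
#' chromatin-enrichment factors tying the contact data to paired RNA-seq
#' counts.
#'
#' @param n_chrom,chrom_length Genome: number of chromosomes and their
#'   common length (bp).
#' @param placement_bin Bin width (bp) used for contact placement.
#' @param n_rna Total RNAs.
#' @param class_counts Named vector of roster sizes per RNA class; must
#'   sum to `n_rna`.
#' @param expr_sdlog Log-normal sd of baseline expression weights.
#' @param depth Contacts per sample.
#' @param replicates Replicates per cell state (states are ES and DE).
#' @param eta_chr Chromosome intercepts of the trans-rate logit
#'   (default: rates 0.30..0.40 across chromosomes).
#' @param eta_expr Coefficient on ln(total contacts).
#' @param gamma Beta-binomial overdispersion (intraclass correlation).
#' @param kernel_alpha,kernel_delta0,kernel_floor Truncated power-law
#'   kernel parameters (see [power_law_kernel()]).
#' @param bias_sdlog Log-normal sd of the per-bin DNA bias.
#' @param gene_length_range Gene body lengths (bp), uniform.
#' @param n_trans_deloc,trans_deloc_offset,n_trans_ultra,trans_ultra_offset
#'   Planted trans effects (counts and logit offsets).
#' @param n_cis_deloc,cis_deloc_offset,n_cis_ultra,cis_ultra_offset
#'   Planted cis effects (log-odds tilt of the far cis mass).
#' @param cis_far_D Travel-distance threshold (bp) defining far cis
#'   contacts for the planted tilt.
#' @param n_xist,xist_trans_factor,xist_cis_offset XIST-like RNAs:
#'   trans mass multiplied by `xist_trans_factor` (approximately zero,
#'   kept positive to avoid degenerate likelihoods) and cis far mass
#'   tilted up.
#' @param n_peak,peak_factor,peaks_per_rna,peak_width,peak_min_dist,peak_max_dist
#'   Planted distal peaks: `peak_width` regions 0.5-1.5 Mb from the TSS
#'   whose placement probability is multiplied by `peak_factor`.
#' @param peak_expr_boost,planted_expr_boost Expression multipliers for
#'   peak-bearing and other planted-effect RNAs, keeping their signal
#'   quantifiable at desk-scale depth.
#' @param frac_de,de_lfc Two-state expression dynamics: fraction of RNAs
#'   differentially expressed (half up in each state) with log fold
#'   change `de_lfc`; others get small N(0, 0.1) log changes.
#' @param n_enriched,n_depleted,enrich_factor Genes with planted
#'   chromatin enrichment (ChAR:RNA-seq abundance ratio `enrich_factor`)
#'   or depletion (1/`enrich_factor`).
#' @param rnaseq_depth,rnaseq_replicates Paired total-RNA-seq counts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 3, chrom_length = 3e7,
                       placement_bin = 1e4, n_rna = 500,
                       class_counts = c(mRNA = 400, lncRNA = 70,
                                        ncRNA = 30),
                       expr_sdlog = 1, depth = 2e5, replicates = 2,
                       eta_chr = NULL, eta_expr = 0.1, gamma = 0.02,
                       kernel_alpha = 1.2, kernel_delta0 = 5e3,
                       kernel_floor = 0.05, bias_sdlog = 0.5,
                       gene_length_range = c(1e4, 5e4),
                       n_trans_deloc = 10, trans_deloc_offset = 2.5,
                       n_trans_ultra = 10, trans_ultra_offset = -2.5,
                       n_cis_deloc = 10, cis_deloc_offset = 2.5,
                       n_cis_ultra = 10, cis_ultra_offset = -2.5,
                       cis_far_D = 1e6,
                       n_xist = 1, xist_trans_factor = 1e-3,
                       xist_cis_offset = 3,
                       n_peak = 5, peak_factor = 5, peaks_per_rna = 1,
                       peak_width = 1e5, peak_min_dist = 5e5,
                       peak_max_dist = 1.5e6, peak_expr_boost = 25,
                       planted_expr_boost = 4,
                       frac_de = 0.2, de_lfc = log(4),
                       n_enriched = 25, n_depleted = 25,
                       enrich_factor = 8,
                       rnaseq_depth = 2e5, rnaseq_replicates = 2) {
  stopifnot(sum(class_counts) == n_rna, depth > 0, gamma >= 0, gamma < 1)
  if (is.null(eta_chr)) {
    eta_chr <- qlogis(seq(0.30, 0.40, length.out = n_chrom))
  }
  stopifnot(length(eta_chr) == n_chrom)
  n_planted_lnc <- n_trans_deloc + n_trans_ultra + n_cis_deloc +
    n_cis_ultra + n_xist
  if (n_planted_lnc > class_counts["lncRNA"]) {
    stop("more planted lncRNA effects than lncRNAs in the roster")
  }
  if (n_peak > class_counts["ncRNA"]) {
    stop("more peak RNAs than ncRNAs in the roster")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_rna, " RNAs, ", x$n_chrom, " x ",
      format(x$chrom_length, big.mark = ","), " bp, ",
      format(x$depth, big.mark = ","), " contacts/sample\n", sep = "")
  invisible(x)
}

# Lay out non-overlapping genes in equal slots along each chromosome.
place_genes <- function(cfg, genome) {
  chroms <- genome_names(genome)
  chrom_of <- rep(chroms, length.out = cfg$n_rna)
  gene_id <- sprintf("gene%04d", seq_len(cfg$n_rna))
  start <- numeric(cfg$n_rna)
  len <- runif(cfg$n_rna, cfg$gene_length_range[1], cfg$gene_length_range[2])
  for (ch in chroms) {
    idx <- which(chrom_of == ch)
    slot <- cfg$chrom_length / length(idx)
    len[idx] <- pmin(len[idx], slot * 0.8)
    start[idx] <- (seq_along(idx) - 1) * slot +
      runif(length(idx), 0, slot - len[idx])
  }
  classes <- sample(rep(names(cfg$class_counts), cfg$class_counts))
  gene_models(gene_id, chrom_of, sample(c("+", "-"), cfg$n_rna, TRUE),
              floor(start), floor(start + len), classes, genome = genome)
}

assign_planted <- function(cfg, gm) {
  planted <- rep("neutral", nrow(gm))
  trans_offset <- numeric(nrow(gm))
  cis_offset <- numeric(nrow(gm))
  lnc <- sample(which(gm$rna_class == "lncRNA"))
  take <- function(n) {
    out <- lnc[seq_len(n)]
    lnc <<- lnc[-seq_len(n)]
    out
  }
  i <- take(cfg$n_trans_deloc)
  planted[i] <- "trans_deloc"; trans_offset[i] <- cfg$trans_deloc_offset
  i <- take(cfg$n_trans_ultra)
  planted[i] <- "trans_ultra"; trans_offset[i] <- cfg$trans_ultra_offset
  i <- take(cfg$n_cis_deloc)
  planted[i] <- "cis_deloc"; cis_offset[i] <- cfg$cis_deloc_offset
  i <- take(cfg$n_cis_ultra)
  planted[i] <- "cis_ultra"; cis_offset[i] <- cfg$cis_ultra_offset
  i <- take(cfg$n_xist)
  planted[i] <- "xist"; cis_offset[i] <- cfg$xist_cis_offset
  peak_rna <- sample(which(gm$rna_class == "ncRNA"), cfg$n_peak)
  planted[peak_rna] <- "peak"
  list(planted = planted, trans_offset = trans_offset,
       cis_offset = cis_offset, peak_rna = peak_rna)
}

#' Generate a ground-truth-annotated synthetic contact dataset
#'
#' Draws, for two cell states with replicated samples, RNA-DNA contact
#' records with the statistical structure assumed by the analysis: (i)
#' per-RNA totals from multinomial sampling of state-specific expression
#' weights; (ii) a beta-binomial split of each RNA's contacts into cis
#' and trans with logit rate = chromosome intercept + eta_expr ln(N) +
#' planted offset; (iii) cis placement by a bin-level multinomial
#' proportional to DNA bias times the distance kernel summed over source
#' positions in the gene body, with planted peak mass and far-mass tilt;
#' (iv) trans placement proportional to the DNA bias (XIST-like RNAs
#' get their trans mass multiplied by ~1e-3 at the split). Paired
#' RNA-seq counts are drawn so that each gene's ChAR:RNA-seq abundance
#' ratio equals its chromatin-enrichment factor times a shared baseline.
#' Fully deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `records` (tibble over all samples), `gene_models`,
#'   `genome`, `sample_info`, `truth` (per-RNA planted labels and effect
#'   sizes), `peaks`, `bias` (per placement-bin tibble), `kernel`,
#'   `charseq_gene_counts`, `rnaseq_counts`, `rnaseq_info`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  cfg <- config
  set.seed(seed)
  genome <- genome_layout(paste0("chr", seq_len(cfg$n_chrom)),
                          rep(cfg$chrom_length, cfg$n_chrom))
  gm <- place_genes(cfg, genome)
  pl <- assign_planted(cfg, gm)
  kernel <- power_law_kernel(cfg$kernel_alpha, cfg$kernel_delta0,
                             max_dist = cfg$chrom_length,
                             floor_weight = cfg$kernel_floor)

  scheme <- bin_scheme_uniform(genome, cfg$placement_bin)
  bins <- scheme_bins(scheme)
  bias_raw <- rlnorm(nrow(bins), 0, cfg$bias_sdlog)
  bias_v <- bias_raw / sum(bias_raw)
  bin_idx <- split(seq_len(nrow(bins)), bins$chrom)

  # planted distal peaks: peak_width regions on the source chromosome,
  # peak_min_dist..peak_max_dist away from the RNA's TSS
  peaks <- list()
  peak_tab <- list()
  for (i in pl$peak_rna) {
    idx <- bin_idx[[gm$chrom[i]]]
    bins_i <- integer(0)
    reg <- list()
    for (k in seq_len(cfg$peaks_per_rna)) {
      repeat {
        d <- runif(1, cfg$peak_min_dist, cfg$peak_max_dist)
        side <- sample(c(-1, 1), 1)
        lo <- gm$tss[i] + side * d - (side < 0) * cfg$peak_width
        hi <- lo + cfg$peak_width
        if (lo >= 0 && hi <= cfg$chrom_length) break
      }
      bins_i <- union(bins_i, idx[bins$mid[idx] >= lo & bins$mid[idx] < hi])
      reg[[k]] <- tibble(gene_id = gm$gene_id[i], chrom = gm$chrom[i],
                         start = lo, end = hi, factor = cfg$peak_factor)
    }
    peaks[[gm$gene_id[i]]] <- bins_i
    peak_tab[[gm$gene_id[i]]] <- bind_rows(reg)
  }
  peak_tab <- bind_rows(peak_tab)

  # expression dynamics; planted-effect RNAs are given quantifiable
  # abundance (peaks especially so, as their signal is a small fraction
  # of their contacts)
  w0 <- rlnorm(cfg$n_rna, 0, cfg$expr_sdlog)
  w0[pl$peak_rna] <- w0[pl$peak_rna] * cfg$peak_expr_boost
  other_planted <- pl$planted != "neutral" & pl$planted != "peak"
  w0[other_planted] <- w0[other_planted] * cfg$planted_expr_boost
  n_de <- round(cfg$frac_de * cfg$n_rna / 2)
  de_label <- rep("stable", cfg$n_rna)
  up_es <- sample(cfg$n_rna, n_de)
  up_de <- sample(setdiff(seq_len(cfg$n_rna), up_es), n_de)
  expr_lfc <- rnorm(cfg$n_rna, 0, 0.1)
  expr_lfc[up_es] <- -cfg$de_lfc
  expr_lfc[up_de] <- cfg$de_lfc
  de_label[up_es] <- "ES"
  de_label[up_de] <- "DE"
  w_state <- list(ES = w0 * exp(-expr_lfc / 2),
                  DE = w0 * exp(expr_lfc / 2))

  # chromatin enrichment factors for the RNA-seq pairing
  enrich <- rep(1, cfg$n_rna)
  pick <- sample(cfg$n_rna, cfg$n_enriched + cfg$n_depleted)
  enrich[pick[seq_len(cfg$n_enriched)]] <- cfg$enrich_factor
  enrich[pick[cfg$n_enriched + seq_len(cfg$n_depleted)]] <-
    1 / cfg$enrich_factor

  sample_info <- tibble(
    sample_id = paste0(rep(c("ES", "DE"), each = cfg$replicates),
                       "_rep", rep(seq_len(cfg$replicates), 2)),
    state = rep(c("ES", "DE"), each = cfg$replicates),
    replicate = rep(seq_len(cfg$replicates), 2)
  )

  is_xist <- pl$planted == "xist"

  # cis placement probabilities are sample-invariant; compute once per RNA
  cis_p <- vector("list", cfg$n_rna)
  for (i in seq_len(cfg$n_rna)) {
    ch <- gm$chrom[i]
    idx <- bin_idx[[ch]]
    src <- gm$start[i] +
      (gm$end[i] - gm$start[i]) * seq(0.05, 0.95, length.out = 15)
    p <- cis_probabilities(src, kernel, bias_v[idx], bins$mid[idx])
    if (!is.null(peaks[[gm$gene_id[i]]])) {
      at <- match(peaks[[gm$gene_id[i]]], idx)
      p[at] <- p[at] * cfg$peak_factor
    }
    if (pl$cis_offset[i] != 0) {
      far <- abs(bins$mid[idx] - gm$tss[i]) > cfg$cis_far_D
      p[far] <- p[far] * exp(pl$cis_offset[i])
    }
    cis_p[[i]] <- p / sum(p)
  }

  records <- vector("list", nrow(sample_info))
  char_counts <- matrix(0L, cfg$n_rna, nrow(sample_info),
                        dimnames = list(gm$gene_id, sample_info$sample_id))
  for (s in seq_len(nrow(sample_info))) {
    st <- sample_info$state[s]
    n_i <- drop(rmultinom(1, cfg$depth, w_state[[st]]))
    char_counts[, s] <- n_i
    per_rna <- vector("list", cfg$n_rna)
    for (i in which(n_i > 0)) {
      n <- n_i[i]
      ch <- gm$chrom[i]
      ci <- match(ch, genome_names(genome))
      pi_t <- plogis(cfg$eta_chr[ci] + cfg$eta_expr * log(n) +
                       pl$trans_offset[i])
      if (is_xist[i]) pi_t <- pi_t * cfg$xist_trans_factor
      if (cfg$n_chrom == 1) pi_t <- 0  # no trans space on a 1-chromosome genome
      theta <- if (cfg$gamma < 1e-12 || pi_t == 0) pi_t else {
        sh <- 1 / cfg$gamma - 1
        rbeta(1, pi_t * sh, (1 - pi_t) * sh)
      }
      n_trans <- rbinom(1, n, theta)
      n_cis <- n - n_trans

      dna_chrom <- character(n)
      dna_pos <- numeric(n)
      if (n_cis > 0) {
        idx <- bin_idx[[ch]]
        cnt <- drop(rmultinom(1, n_cis, cis_p[[i]]))
        at <- rep(idx[cnt > 0], cnt[cnt > 0])
        dna_chrom[seq_len(n_cis)] <- ch
        dna_pos[seq_len(n_cis)] <-
          floor(runif(n_cis, bins$start[at], bins$end[at]))
      }
      if (n_trans > 0) {
        idx <- which(bins$chrom != ch)
        p <- bias_v[idx] / sum(bias_v[idx])
        cnt <- drop(rmultinom(1, n_trans, p))
        at <- rep(idx[cnt > 0], cnt[cnt > 0])
        dna_chrom[n_cis + seq_len(n_trans)] <- bins$chrom[at]
        dna_pos[n_cis + seq_len(n_trans)] <-
          floor(runif(n_trans, bins$start[at], bins$end[at]))
      }
      per_rna[[i]] <- tibble(
        rna_gene_id = gm$gene_id[i],
        rna_chrom = ch,
        rna_pos = floor(runif(n, gm$start[i], gm$end[i])),
        rna_strand = gm$strand[i],
        dna_chrom = dna_chrom,
        dna_pos = dna_pos,
        dna_strand = sample(c("+", "-"), n, TRUE)
      )
    }
    rec <- bind_rows(per_rna)
    rec$read_id <- sprintf("%s:%07d", sample_info$sample_id[s],
                           seq_len(nrow(rec)))
    rec$annotation_class <- "exon"
    rec$sample_id <- sample_info$sample_id[s]
    records[[s]] <- select(rec, "read_id", "rna_gene_id", "rna_chrom",
                           "rna_pos", "rna_strand", "dna_chrom", "dna_pos",
                           "dna_strand", "annotation_class", "sample_id")
  }
  records <- bind_rows(records)

  # paired total-RNA-seq counts: ChAR abundance / enrichment factor
  rnaseq_info <- tibble(
    sample_id = paste0("rna_", rep(c("ES", "DE"),
                                   each = cfg$rnaseq_replicates),
                       "_rep", rep(seq_len(cfg$rnaseq_replicates), 2)),
    state = rep(c("ES", "DE"), each = cfg$rnaseq_replicates),
    replicate = rep(seq_len(cfg$rnaseq_replicates), 2)
  )
  rnaseq_counts <- matrix(0L, cfg$n_rna, nrow(rnaseq_info),
                          dimnames = list(gm$gene_id,
                                          rnaseq_info$sample_id))
  for (s in seq_len(nrow(rnaseq_info))) {
    w <- w_state[[rnaseq_info$state[s]]] / enrich
    rnaseq_counts[, s] <- drop(rmultinom(1, cfg$rnaseq_depth, w / sum(w)))
  }

  truth <- tibble(
    gene_id = gm$gene_id, rna_class = gm$rna_class,
    planted = pl$planted, trans_offset = pl$trans_offset,
    cis_offset = pl$cis_offset, expr_lfc = expr_lfc,
    de_label = de_label, enrich_factor = enrich
  )
  list(
    records = records, gene_models = gm, genome = genome,
    sample_info = sample_info, truth = truth, peaks = peak_tab,
    bias = mutate(bins, bias = bias_v), kernel = kernel,
    charseq_gene_counts = char_counts, rnaseq_counts = rnaseq_counts,
    rnaseq_info = rnaseq_info, config = cfg
  )
}

#' Write a simulated dataset to plain-text files
#'
#' Writes one pairs file per sample, a GTF of gene models, a chrom.sizes
#' file, the RNA-seq count table, and the planted-truth table.
#'
#' @param sim Output of [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (s in sim$sample_info$sample_id) {
    write_pairs(sim$records[sim$records$sample_id == s, ],
                file.path(outdir, paste0(s, ".pairs")))
  }
  write_gene_models_gtf(sim$gene_models, file.path(outdir, "genes.gtf"))
  write_chrom_sizes(sim$genome, file.path(outdir, "genome.chrom.sizes"))
  utils::write.table(
    data.frame(gene_id = rownames(sim$rnaseq_counts), sim$rnaseq_counts,
               check.names = FALSE),
    file.path(outdir, "rnaseq_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Simulate far-contact counts from a fitted beta-binomial null
#'
#' For each supplied covariate row, draws a rate from the Beta prior
#' implied by the fit at those covariates and then a binomial count,
#' i.e. `N_far ~ BetaBinomial(N, pi_model, gamma)` independently across
#' RNAs.
#'
#' @param fit A `betabin_glm_fit`.
#' @param covariates Tibble with columns `chrom` and `N` (and optionally
#'   `gene_id`, `rna_class`).
#' @param seed Integer seed.
#' @return Tibble shaped like [compute_far_counts()] output.
#' @export
simulate_null_glm_counts <- function(fit, covariates, seed = 1) {
  set.seed(seed)
  n <- covariates$N
  lnN <- log(n)
  pi <- predict_pi_model(fit, covariates$chrom, lnN)
  if (fit$gamma <= 0) {
    warning("gamma <= 0; falling back to binomial sampling")
    theta <- pi
  } else {
    sh <- 1 / fit$gamma - 1
    theta <- rbeta(length(n), pi * sh, (1 - pi) * sh)
  }
  k <- rbinom(length(n), n, theta)
  tibble(
    gene_id = covariates[["gene_id"]] %||% sprintf("sim%05d", seq_along(n)),
    sample_id = "null_sim",
    chrom = covariates$chrom,
    rna_class = covariates[["rna_class"]] %||% "mRNA",
    N = n, N_far = k, lnN = lnN, mode = fit$mode %||% "trans", D = NA_real_
  )
}

#' Recall/precision report against planted truth
#'
#' Confusion counts of predicted labels against planted labels, per
#' label class. Both inputs must cover the same identifiers.
#'
#' @param truth Tibble with `gene_id` and a `label` column.
#' @param results Tibble with `gene_id` and a `label` column.
#' @return Tibble per label: `n_truth`, `n_called`, `tp`, `fp`, `fn`,
#'   `recall`, `precision`, `fdr`.
#' @export
truth_report <- function(truth, results) {
  if (!all(truth$gene_id %in% results$gene_id)) {
    stop("results do not cover the truth roster")
  }
  m <- inner_join(select(truth, "gene_id", truth_label = "label"),
                  select(results, "gene_id", called_label = "label"),
                  by = "gene_id")
  labels <- sort(unique(c(m$truth_label, m$called_label)))
  bind_rows(lapply(labels, function(L) {
    tp <- sum(m$truth_label == L & m$called_label == L)
    fp <- sum(m$truth_label != L & m$called_label == L)
    fn <- sum(m$truth_label == L & m$called_label != L)
    tibble(
      label = L, n_truth = tp + fn, n_called = tp + fp,
      tp = tp, fp = fp, fn = fn,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_
    )
  }))
}

#' Synthetic caRNA-gene edge set with a planted positive-edge excess
#'
#' Generates edges whose contact dynamics align with the target gene's
#' expression label more often than chance by a chosen fold. Gene labels
#' are ES / DE / stable with `prop_de` split evenly between ES and DE;
#' contacts of edges at ES (DE) genes are upES (upDE) with probability
#' `(1 + t) / 2` where `t = fold - 1`, and 50/50 at stable genes, so the
#' expected positive fraction is exactly `fold` times its shuffled-label
#' expectation. One distinct gene per edge.
#'
#' @param n_edges Number of edges.
#' @param fold Planted fold excess of positive edges, in [0, 2].
#' @param prop_de Fraction of genes differentially expressed.
#' @param seed Integer seed.
#' @return Edge tibble with `rna_id`, `gene_id`, `contact_class`,
#'   `gene_class`, suitable for [edge_sign_enrichment()].
#' @export
simulate_edge_set <- function(n_edges, fold = 1, prop_de = 0.3, seed = 1) {
  stopifnot(fold >= 0, fold <= 2)
  set.seed(seed)
  t <- fold - 1
  gene_class <- sample(c("ES", "DE", "stable"), n_edges, replace = TRUE,
                       prob = c(prop_de / 2, prop_de / 2, 1 - prop_de))
  aligned <- runif(n_edges) < (1 + t) / 2
  contact_class <- ifelse(
    gene_class == "ES", ifelse(aligned, "upES", "upDE"),
    ifelse(gene_class == "DE", ifelse(aligned, "upDE", "upES"),
           sample(c("upES", "upDE"), n_edges, replace = TRUE))
  )
  tibble(
    rna_id = sprintf("rna%05d", seq_len(n_edges)),
    gene_id = sprintf("tgt%05d", seq_len(n_edges)),
    contact_class = contact_class,
    gene_class = gene_class
  )
}


#' Null tail-probability calibration of the delocalization caller
#'
#' End-to-end calibration check of the empirical-Bayes tail probability:
#' simulates a training cohort of mRNA-like RNAs from a beta-binomial
#' null (chromosome intercepts + log-expression covariate, shared
#' overdispersion), fits the beta-binomial GLM on it, simulates a fresh
#' null cohort from the *fitted* model, computes each RNA's
#' posterior-vs-prior tail probability by quadrature, and reports the
#' fraction at or below `level`. Under a calibrated caller this
#' fraction matches `level` up to binomial noise: the caller cuts off
#' the extreme tail of the training-class score distribution.
#'
#' @param n Cohort size (both training and null cohorts).
#' @param seed Integer seed.
#' @param level Classification level (default 0.05).
#' @param eta_chr True chromosome intercepts of the generating null
#'   (defaults to rates 0.30/0.35/0.40 on three chromosomes).
#' @param eta_expr True log-expression coefficient.
#' @param gamma True overdispersion.
#' @param n_range Range of per-RNA totals, drawn log-uniformly.
#' @return List with `fraction` (of null RNAs at or below `level`),
#'   `percent`, `n`, `fit` (the trained GLM), and the tail-probability
#'   table.
#' @export
null_tail_calibration <- function(n = 2000, seed = 1, level = 0.05,
                                  eta_chr = qlogis(c(0.30, 0.35, 0.40)),
                                  eta_expr = 0.05, gamma = 0.02,
                                  n_range = c(500, 50000)) {
  set.seed(seed)
  chroms <- paste0("chr", seq_along(eta_chr))
  draw_cov <- function() {
    tibble(
      chrom = sample(chroms, n, replace = TRUE),
      N = round(exp(runif(n, log(n_range[1]), log(n_range[2]))))
    )
  }
  true_fit <- structure(
    list(eta_chr = setNames(eta_chr, chroms), eta_expr = eta_expr,
         gamma = gamma, mode = "trans"),
    class = "betabin_glm_fit"
  )
  seeds <- sample.int(.Machine$integer.max, 2)
  train <- simulate_null_glm_counts(true_fit, draw_cov(), seed = seeds[1])
  fit <- fit_betabin_glm(train, training_class = "mRNA", min_total = 50)
  nulls <- simulate_null_glm_counts(fit, draw_cov(), seed = seeds[2])
  tails <- tail_probability(posterior_rate(fit, nulls))
  frac <- mean(tails$p_deloc <= level)
  list(fraction = frac, percent = 100 * frac, n = n, level = level,
       fit = fit, tails = tails)
}
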
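#' Proximal regulatory regions around gene TSSs
#'
#' Builds for each gene a strand-oriented window running from `upstream`
#' bp before the TSS to `downstream` bp after it in the direction of
#' transcription (default 10 kb + 90 kb = a 100 kb window). Genomic
#' coordinates are reversed for "-" strand genes. Windows are clipped at
#' chromosome bounds and flagged when clipping occurred.
#'
#' @param gene_models Gene-model tibble.
#' @param genome A [genome_layout()].
#' @param upstream,downstream Window extents in bp.
#' @return Tibble per gene: `gene_id`, `chrom`, `start`, `end`,
#'   `clipped`.
#' @export
build_prr <- function(gene_models, genome, upstream = 1e4,
                      downstream = 9e4) {
  tss <- gene_models$tss
  start <- ifelse(gene_models$strand == "+", tss - upstream,
                  tss - downstream)
  end <- ifelse(gene_models$strand == "+", tss + downstream,
                tss + upstream)
  len <- chrom_length(genome, gene_models$chrom)
  cs <- pmax(start, 0)
  ce <- pmin(end, len)
  was_clipped <- cs != start | ce != end
  tibble(
    gene_id = gene_models$gene_id, chrom = gene_models$chrom,
    start = cs, end = ce, clipped = was_clipped
  )
}

#' caRNA x gene interactome over proximal regulatory regions
#'
#' Counts, for every (caRNA, gene) pair, the contact records of the RNA
#' whose DNA-side position falls inside the gene's proximal regulatory
#' region. A contact inside two overlapping regions counts once for each
#' gene.
#'
#' @param records Contact-record tibble.
#' @param prr_windows Tibble from [build_prr()].
#' @return Sparse matrix caRNAs x genes of contact counts.
#' @export
build_gene_interactome <- function(records, prr_windows) {
  rna_ids <- sort(unique(records$rna_gene_id))
  pts <- GRanges(records$dna_chrom,
                 IRanges(records$dna_pos + 1, width = 1))
  win <- GRanges(prr_windows$chrom,
                 IRanges(prr_windows$start + 1, prr_windows$end))
  ov <- findOverlaps(pts, win)
  i <- match(records$rna_gene_id[queryHits(ov)], rna_ids)
  j <- subjectHits(ov)
  sparseMatrix(i = i, j = j, x = rep(1, length(i)),
               dims = c(length(rna_ids), nrow(prr_windows)),
               dimnames = list(rna_ids, prr_windows$gene_id))
}

#' Classify caRNA-gene edges by sign
#'
#' Combines the dynamic class of each differential contact with the
#' expression dynamics of the caRNA and of the contacted gene. Edge sign
#' follows the truth table: positive when the contact and the gene move
#' up in the same state; negative when they move up in opposite states;
#' neutral when the gene is stable. Contacts whose own dynamic class is
#' stable yield no edge.
#'
#' @param contacts Tibble with `rna_id`, `gene_id`, `contact_class` in
#'   `upES`/`upDE`/`stable`.
#' @param rna_de Tibble with `rna_id`, `rna_class` in `ES`/`DE`/`stable`.
#' @param gene_de Tibble with `gene_id`, `gene_class` in
#'   `ES`/`DE`/`stable`.
#' @return Edge tibble with `sign` in `positive`/`negative`/`neutral`.
#' @export
classify_edges <- function(contacts, rna_de, gene_de) {
  ok_contact <- c("upES", "upDE", "stable")
  ok_de <- c("ES", "DE", "stable")
  if (!all(contacts$contact_class %in% ok_contact)) {
    stop("contact_class must be one of ", paste(ok_contact, collapse = "/"))
  }
  if (!all(rna_de$rna_class %in% ok_de) ||
      !all(gene_de$gene_class %in% ok_de)) {
    stop("DE classes must be one of ", paste(ok_de, collapse = "/"))
  }
  edges <- contacts |>
    filter(.data$contact_class != "stable") |>
    left_join(rna_de, by = "rna_id") |>
    left_join(gene_de, by = "gene_id")
  if (anyNA(edges$rna_class) || anyNA(edges$gene_class)) {
    stop("missing DE labels for some edges")
  }
  mutate(edges, sign = dplyr::case_when(
    .data$gene_class == "stable" ~ "neutral",
    (.data$contact_class == "upES" & .data$gene_class == "ES") |
      (.data$contact_class == "upDE" & .data$gene_class == "DE") ~
      "positive",
    TRUE ~ "negative"
  ))
}

#' Positive-edge enrichment against a shuffled null
#'
#' Compares the observed fraction of positive edges with its expectation
#' under a null where the differential-expression labels of the target
#' genes are shuffled across genes (preserving label counts; the null
#' mean averages `n_perm` permutations). The fold enrichment is the
#' observed fraction over the null mean; its confidence interval comes
#' from resampling edges with replacement `n_boot` times, with the
#' per-resample null computed in closed form from the resampled label
#' and contact-class composition (the permutation mean is linear in
#' these, so the closed form equals the average over permutations). The
#' enrichment is significant when the CI excludes 1.
#'
#' @param edges Edge tibble from [classify_edges()]; callers should
#'   restrict it to caRNAs whose own expression is differential, as the
#'   enrichment is defined on that subset.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param n_perm Label permutations for the null mean (default 1000).
#' @param seed Integer seed.
#' @param conf_level Confidence level of the CI.
#' @return A tibble with `observed_fraction`, `null_fraction`, `fold`,
#'   `ci_lo`, `ci_hi`, `p_perm`, `significant`, `n_edges`, `n_boot`,
#'   `seed`.
#' @export
edge_sign_enrichment <- function(edges, n_boot = 10000, n_perm = 1000,
                                 seed = 1, conf_level = 0.95) {
  if (nrow(edges) < 10) stop("too few edges for enrichment analysis")
  set.seed(seed)
  genes <- distinct(edges, .data$gene_id, .data$gene_class)
  gidx <- match(edges$gene_id, genes$gene_id)
  is_up_es <- edges$contact_class == "upES"
  is_up_de <- edges$contact_class == "upDE"
  pos_frac <- function(gene_class) {
    mean((is_up_es & gene_class == "ES") |
           (is_up_de & gene_class == "DE"))
  }
  observed <- pos_frac(genes$gene_class[gidx])

  perm_frac <- vapply(seq_len(n_perm), function(k) {
    pos_frac(sample(genes$gene_class)[gidx])
  }, numeric(1))
  null_mean <- mean(perm_frac)
  fold <- observed / null_mean
  p_perm <- (sum(perm_frac >= observed) + 1) / (n_perm + 1)

  # closed-form permutation mean for a resample: linearity of the mean
  # over edges gives  (n_upES * pES + n_upDE * pDE) / n  with label
  # proportions taken over genes
  p_es <- mean(genes$gene_class == "ES")
  p_de <- mean(genes$gene_class == "DE")
  n <- nrow(edges)
  edge_pos <- (is_up_es & genes$gene_class[gidx] == "ES") |
    (is_up_de & genes$gene_class[gidx] == "DE")
  boot_fold <- vapply(seq_len(n_boot), function(k) {
    idx <- sample.int(n, n, replace = TRUE)
    ob <- mean(edge_pos[idx])
    nu <- (sum(is_up_es[idx]) * p_es + sum(is_up_de[idx]) * p_de) / n
    ob / nu
  }, numeric(1))
  alpha <- (1 - conf_level) / 2
  ci <- quantile(boot_fold, c(alpha, 1 - alpha), names = FALSE)
  tibble(
    observed_fraction = observed, null_fraction = null_mean, fold = fold,
    ci_lo = ci[1], ci_hi = ci[2], p_perm = p_perm,
    significant = ci[1] > 1 | ci[2] < 1,
    n_edges = n, n_boot = n_boot, seed = seed
  )
}

#' Metagene contact profile around genomic features
#'
#' Averages one RNA's contact counts in windows centered on a set of
#' genomic features, binned at `bin_size`, and normalizes by the RNA's
#' genome-wide mean contacts per bin so that background level is 1.
#'
#' @param records Contact-record tibble.
#' @param rna_id RNA whose contacts are profiled.
#' @param centers Tibble with `chrom`, `pos` feature centers.
#' @param half_window Half-width of the profiled window (bp).
#' @param bin_size Bin width (bp); `2 * half_window / bin_size` bins.
#' @param genome A [genome_layout()].
#' @return Tibble with `offset` (bin center relative to the feature) and
#'   `enrichment` (mean count per bin / genome-wide mean per bin).
#' @export
metagene_profile <- function(records, rna_id, centers, half_window,
                             bin_size, genome) {
  stopifnot(nrow(centers) >= 1)
  rec <- records[records$rna_gene_id == rna_id, , drop = FALSE]
  breaks <- seq(-half_window, half_window, by = bin_size)
  offsets <- head(breaks, -1) + bin_size / 2
  if (nrow(rec) == 0) {
    warning("no records for RNA '", rna_id, "'; returning flat zero ",
            "profile")
    return(tibble(offset = offsets, enrichment = 0))
  }
  acc <- numeric(length(offsets))
  for (i in seq_len(nrow(centers))) {
    d <- rec$dna_pos[rec$dna_chrom == centers$chrom[i]] - centers$pos[i]
    d <- d[d >= -half_window & d < half_window]
    acc <- acc + tabulate(findInterval(d, breaks), nbins = length(offsets))
  }
  mean_per_bin <- acc / nrow(centers)
  background <- nrow(rec) / (genome_length(genome) / bin_size)
  tibble(offset = offsets, enrichment = mean_per_bin / background)
}
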
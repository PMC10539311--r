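#' Build an interaction count table from per-sample contact maps
#'
#' Rows are (RNA, bin) interactions, columns are samples. Interactions
#' for which fewer than `min_samples` of the filter samples have at least
#' `min_count` reads are excluded (the filter is evaluated on
#' `filter_on` samples only, e.g. the observed maps when model or
#' expression-only columns are present).
#'
#' @param maps Named list of `contact_matrix` objects with identical
#'   dimensions; names are sample ids.
#' @param sample_info Tibble with a `sample_id` column matching
#'   `names(maps)` plus design covariates (`cell`, and e.g. `mapType` or
#'   `src`).
#' @param min_count,min_samples Row filter: keep rows with >=
#'   `min_count` reads in >= `min_samples` filter samples.
#' @param filter_on Character vector of sample ids the filter is
#'   evaluated on (default: all samples).
#' @return List with `counts` (matrix rows x samples), `rows` (tibble
#'   `rna`, `bin`), `samples` (the sample_info, ordered as columns), and
#'   `n_excluded`.
#' @export
build_interaction_table <- function(maps, sample_info, min_count = 10,
                                    min_samples = 2, filter_on = NULL) {
  stopifnot(all(sample_info$sample_id %in% names(maps)))
  if (!"cell" %in% colnames(sample_info)) {
    stop("sample covariates must include 'cell'")
  }
  maps <- maps[sample_info$sample_id]
  dims <- dim(maps[[1]]$counts)
  for (m in maps) stopifnot(identical(dim(m$counts), dims))
  if (is.null(filter_on)) filter_on <- sample_info$sample_id

  # candidate rows: nonzero anywhere in the filter samples
  agg <- Reduce(`+`, lapply(maps[filter_on], function(m) m$counts))
  tr <- as(as(agg, "generalMatrix"), "TsparseMatrix")
  cand <- unique(cbind(tr@i + 1L, tr@j + 1L))
  if (nrow(cand) == 0) {
    return(list(counts = matrix(0, 0, length(maps),
                                dimnames = list(NULL, names(maps))),
                rows = tibble(rna = character(), bin = integer()),
                samples = sample_info, n_excluded = 0L))
  }
  extract <- function(m) m$counts[cand]
  filt_counts <- vapply(maps[filter_on], extract, numeric(nrow(cand)))
  if (is.null(dim(filt_counts))) {
    filt_counts <- matrix(filt_counts, nrow = nrow(cand))
  }
  keep <- rowSums(filt_counts >= min_count) >= min_samples
  n_excluded <- sum(!keep)
  cand <- cand[keep, , drop = FALSE]
  counts <- vapply(maps, function(m) m$counts[cand], numeric(nrow(cand)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(cand))
  colnames(counts) <- names(maps)
  list(
    counts = counts,
    rows = tibble(rna = rownames(maps[[1]]$counts)[cand[, 1]],
                  bin = cand[, 2]),
    samples = sample_info,
    n_excluded = n_excluded
  )
}

#' Expression-only contact map
#'
#' Replaces every bin of RNA i with the RNA's total contact count N_i
#' (a row-constant map). Such maps carry the abundance of each RNA but
#' no localization information, and serve as the reference against which
#' relocalization is tested.
#'
#' @param cm A `contact_matrix`.
#' @return A `contact_matrix` with row-constant counts.
#' @export
expression_only_map <- function(cm) {
  n_i <- contact_totals(cm)
  counts <- Matrix(rep(n_i, ncol(cm$counts)), nrow = nrow(cm$counts),
                   dimnames = dimnames(cm$counts))
  contact_matrix(counts, cm$scheme,
                 sample_id = paste0(cm$sample_id %||% "map", "_expr"))
}

#' Median-of-ratios size factors
#'
#' Standard median-of-ratios normalization: each sample's factor is the
#' median across reference rows of the ratio of its count to the row
#' geometric mean. The reference can be restricted to a row subset (rows
#' with any zero are always excluded, as the geometric mean requires all
#' positive counts). Factors are rescaled to geometric mean 1.
#'
#' @param counts Matrix rows x samples.
#' @param row_subset Optional integer or logical index of reference rows.
#' @return Numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts, row_subset = NULL) {
  ref <- if (is.null(row_subset)) counts else counts[row_subset, , drop = FALSE]
  ref <- ref[rowSums(ref <= 0) == 0, , drop = FALSE]
  if (nrow(ref) == 0) {
    stop("no all-positive reference rows for median-of-ratios; ",
         "consider a pseudo-reference fallback")
  }
  log_gm <- rowMeans(log(ref))
  sf <- apply(ref, 2, function(col) exp(median(log(col) - log_gm)))
  sf / exp(mean(log(sf)))
}

# Method-of-moments NB dispersion per row, conditional on design groups.
# Uses normalized counts; var(k/s) ~= mu * mean(1/s) + alpha * mu^2
# within a group of samples sharing covariates.
mom_dispersion <- function(counts, sf, groups) {
  norm <- sweep(counts, 2, sf, "/")
  n_rows <- nrow(counts)
  num <- numeric(n_rows)
  den <- numeric(n_rows)
  wsum <- numeric(n_rows)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    m <- rowMeans(norm[, idx, drop = FALSE])
    v <- apply(norm[, idx, drop = FALSE], 1, var)
    shot <- m * mean(1 / sf[idx])
    w <- length(idx) - 1
    ok <- m > 0
    num[ok] <- num[ok] + w * (v[ok] - shot[ok]) / m[ok]^2
    wsum[ok] <- wsum[ok] + w
  }
  disp <- ifelse(wsum > 0, num / pmax(wsum, 1), 0)
  pmax(disp, 1e-8)
}

#' Negative-binomial GLM test across interactions
#'
#' A per-row negative-binomial log-link GLM engine for interactome-space
#' differential testing. Per row: dispersion is estimated by
#' design-group method of moments, floored at 1e-8, and shrunk 50/50
#' toward the trimmed mean dispersion of rows with similar mean
#' (mean-quantile strata); the GLM is then fit with the dispersion
#' plugged in and log size factors as offsets; the coefficient of
#' interest is tested by a Wald z-test (information-based standard
#' errors, dispersion treated as known). P-values are BH-adjusted across
#' rows. Shrunken log2 fold changes use a zero-centered normal prior
#' whose scale is the empirical SD of the raw LFCs.
#'
#' @param counts Matrix rows x samples (integer counts).
#' @param coldata Tibble/data.frame of per-sample covariates; factor
#'   reference levels determine coefficient meanings.
#' @param design Model formula over `coldata` columns, e.g.
#'   `~ cell + src + cell:src`.
#' @param coef Name of the model-matrix column to test.
#' @param size_factors Optional; estimated from all rows by default.
#' @param shrink Compute shrunken LFCs (default `TRUE`).
#' @param test `"wald"` (default) or `"lrt"`: the likelihood-ratio test
#'   drops the tested column from the design and compares deviances;
#'   it is preferred when a design cell can be all zero (e.g. observed
#'   vs model maps), where the Wald statistic degenerates.
#' @param n_strata Number of mean-quantile strata for dispersion
#'   moderation.
#' @param trim Trim fraction for the stratum mean dispersion.
#' @return Tibble with one row per input row: `base_mean`, `dispersion`,
#'   `lfc` (log2), `lfc_se`, `shrunken_lfc`, `stat`, `pvalue`, `padj`.
#'   Rows that are all zero get `NA` results.
#' @export
nb_glm_test <- function(counts, coldata, design, coef, size_factors = NULL,
                        shrink = TRUE, test = c("wald", "lrt"),
                        n_strata = 20, trim = 0.1) {
  test <- match.arg(test)
  counts <- as.matrix(counts)
  X <- model.matrix(design, data = as.data.frame(coldata))
  if (qr(X)$rank < ncol(X)) stop("design matrix is singular")
  if (!coef %in% colnames(X)) {
    stop("coefficient '", coef, "' not in design columns: ",
         paste(colnames(X), collapse = ", "))
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  off <- log(size_factors)

  groups <- apply(X, 1, paste, collapse = "/")
  disp_raw <- mom_dispersion(counts, size_factors, groups)
  base_mean <- rowMeans(sweep(counts, 2, size_factors, "/"))

  # moderate toward the trimmed mean dispersion of rows with similar
  # mean, then floor at the trend: per-row underestimates of the
  # dispersion inflate the Wald statistic, so shrinkage below the
  # stratum trend is not allowed
  br <- unique(quantile(base_mean, probs = seq(0, 1, length.out = n_strata + 1)))
  stratum <- cut(base_mean, breaks = br, include.lowest = TRUE)
  disp_trend <- tapply(disp_raw, stratum, mean, trim = trim)
  trend_row <- as.numeric(disp_trend[stratum])
  disp <- pmax(0.5 * disp_raw + 0.5 * trend_row, trend_row, 1e-8)

  ci <- match(coef, colnames(X))
  X0 <- X[, -ci, drop = FALSE]
  n_rows <- nrow(counts)
  est <- se <- lrt_stat <- rep(NA_real_, n_rows)
  nonzero <- rowSums(counts) > 0
  for (r in which(nonzero)) {
    fam <- negative.binomial(theta = 1 / disp[r], link = "log")
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, counts[r, ], family = fam, offset = off)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) next
    w <- fit$weights
    V <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
    if (is.null(V)) next
    est[r] <- fit$coefficients[ci]
    se[r] <- sqrt(V[ci, ci])
    if (test == "lrt") {
      fit0 <- tryCatch(
        suppressWarnings(glm.fit(X0, counts[r, ], family = fam,
                                 offset = off)),
        error = function(e) NULL
      )
      if (!is.null(fit0) && fit0$converged) {
        lrt_stat[r] <- max(fit0$deviance - fit$deviance, 0)
      }
    }
  }
  lfc <- est / log(2)
  lfc_se <- se / log(2)
  if (test == "wald") {
    stat <- est / se
    pvalue <- 2 * pnorm(-abs(stat))
  } else {
    stat <- lrt_stat
    pvalue <- pchisq(lrt_stat, df = 1, lower.tail = FALSE)
  }
  padj <- rep(NA_real_, n_rows)
  ok <- !is.na(pvalue)
  padj[ok] <- p.adjust(pvalue[ok], method = "BH")

  shrunken <- lfc
  if (shrink) {
    tau2 <- var(lfc[ok])
    if (is.finite(tau2) && tau2 > 0) {
      shrunken <- lfc * tau2 / (tau2 + lfc_se^2)
    }
  }
  tibble(base_mean = base_mean, dispersion = disp, lfc = lfc,
         lfc_se = lfc_se, shrunken_lfc = shrunken, stat = stat,
         pvalue = pvalue, padj = padj)
}

# Run nb_glm_test per cell state by switching the reference level of the
# cell factor and re-fitting, mirroring the per-state procedure.
per_state_nb_test <- function(tab, design, coef, states, sf,
                              test = "wald") {
  out <- list()
  for (s in states) {
    cd <- tab$samples
    cd$cell <- stats::relevel(factor(cd$cell), ref = s)
    res <- nb_glm_test(tab$counts, cd, design, coef, size_factors = sf,
                       test = test)
    res$state <- s
    out[[s]] <- bind_cols(tab$rows, res)
  }
  bind_rows(out)
}

#' Flag contacts not explained by the generative model
#'
#' Compares observed contact maps against single realizations of the
#' generative model with a per-row NB GLM of design
#' `~ cell + src + cell:src` (`src` = observed vs model; the row filter
#' uses the observed samples only). Within each cell state (reference
#' level switched and the model refit), interactions whose shrunken
#' LFC(observed/model) exceeds `lfc_thresh` with BH-adjusted p below
#' `fdr` are flagged as not explained by the model.
#'
#' @param obs_maps,model_maps Named lists of `contact_matrix` objects
#'   (same names = same biological sample).
#' @param sample_info Tibble with `sample_id`, `cell` for the observed
#'   samples.
#' @param lfc_thresh Flag threshold on the shrunken log2 fold change
#'   (default `log2(1.3)`; set to `1.3` to reproduce a threshold
#'   directly on the LFC value instead).
#' @param fdr BH-adjusted p-value threshold.
#' @param min_count,min_samples Row filter (on observed samples).
#' @return List with `results` (per interaction per state), `flags`
#'   (flagged subset), and `per_rna` (flagged interaction counts per
#'   RNA).
#' @export
flag_model_deviations <- function(obs_maps, model_maps, sample_info,
                                  lfc_thresh = log2(1.3), fdr = 0.05,
                                  min_count = 10, min_samples = 2) {
  if (!all(names(obs_maps) %in% names(model_maps))) {
    stop("model maps missing for some observed samples")
  }
  model_maps <- model_maps[names(obs_maps)]
  maps <- c(obs_maps, setNames(model_maps,
                               paste0(names(model_maps), "_model")))
  si <- bind_rows(
    mutate(sample_info, src = "observed"),
    mutate(sample_info, sample_id = paste0(.data$sample_id, "_model"),
           src = "model")
  )
  si$src <- factor(si$src, levels = c("model", "observed"))
  tab <- build_interaction_table(maps, si, min_count = min_count,
                                 min_samples = min_samples,
                                 filter_on = sample_info$sample_id)
  sf <- estimate_size_factors(tab$counts)
  res <- per_state_nb_test(tab, ~ cell + src + cell:src, "srcobserved",
                           unique(sample_info$cell), sf, test = "lrt")
  res$flagged <- !is.na(res$padj) & res$padj < fdr &
    res$shrunken_lfc > lfc_thresh
  flags <- filter(res, .data$flagged)
  per_rna <- count(flags, .data$rna, .data$state, name = "n_flagged")
  list(results = res, flags = flags, per_rna = per_rna,
       n_tested = nrow(tab$rows))
}

#' Flag relocalization events between cell states
#'
#' Tests whether the between-state dynamics of each interaction exceeds
#' what the RNA's expression change alone explains, by contrasting
#' observed maps with expression-only maps (design
#' `~ cell + mapType + cell:mapType`; the interaction coefficient is the
#' test). Interactions with BH-adjusted interaction p below `fdr` are
#' flagged as relocalization events.
#'
#' @param obs_maps Named list of observed `contact_matrix` objects.
#' @param sample_info Tibble with `sample_id`, `cell`.
#' @param expr_maps Optional expression-only maps (built with
#'   [expression_only_map()] by default).
#' @param fdr BH threshold.
#' @param min_count,min_samples Row filter (observed samples only).
#' @return List with `results`, `flags`, `n_tested`.
#' @export
flag_relocalization <- function(obs_maps, sample_info, expr_maps = NULL,
                                fdr = 0.05, min_count = 10,
                                min_samples = 2) {
  if (is.null(expr_maps)) expr_maps <- lapply(obs_maps, expression_only_map)
  expr_maps <- expr_maps[names(obs_maps)]
  maps <- c(obs_maps, setNames(expr_maps,
                               paste0(names(expr_maps), "_expr")))
  si <- bind_rows(
    mutate(sample_info, mapType = "observed"),
    mutate(sample_info, sample_id = paste0(.data$sample_id, "_expr"),
           mapType = "expressionOnly")
  )
  si$mapType <- factor(si$mapType, levels = c("expressionOnly", "observed"))
  si$cell <- factor(si$cell)
  tab <- build_interaction_table(maps, si, min_count = min_count,
                                 min_samples = min_samples,
                                 filter_on = sample_info$sample_id)
  sf <- estimate_size_factors(tab$counts)
  states <- levels(si$cell)
  coef <- paste0("cell", states[2], ":mapTypeobserved")
  res <- nb_glm_test(tab$counts, si, ~ cell + mapType + cell:mapType,
                     coef, size_factors = sf, test = "lrt")
  res <- bind_cols(tab$rows, res)
  res$flagged <- !is.na(res$padj) & res$padj < fdr
  list(results = res, flags = filter(res, .data$flagged),
       n_tested = nrow(tab$rows))
}

#' Chromatin association scores from paired contact and RNA-seq counts
#'
#' Per-gene comparison of abundance in the chromatin-associated RNA
#' population (RNA side of the contact data) versus the total
#' transcriptome (RNA-seq), with design
#' `~ cell + sequencing + cell:sequencing`. The chromatin association
#' score is the shrunken log2 coefficient of the sequencing covariate,
#' computed per cell state by reference-level switching; a gene is
#' labeled `enriched` when its adjusted p is below `fdr` and the score
#' exceeds `log2(min_fold)` (`depleted` symmetric). The
#' `cell:sequencing` interaction coefficient (change in association
#' between states) is reported alongside.
#'
#' @param char_counts,rna_counts Gene x sample count matrices for the
#'   contact-derived and RNA-seq libraries; shared rownames.
#' @param char_info,rna_info Tibbles with `sample_id`, `cell` for each
#'   matrix's columns.
#' @param fdr BH threshold for labels.
#' @param min_fold Fold-change threshold for labels (score threshold is
#'   `log2(min_fold)`).
#' @param min_total Genes with fewer combined counts are excluded.
#' @param sf_min_total Size-factor reference: genes with at least this
#'   many combined counts.
#' @return Tibble per (gene, state): `score` (shrunken), `padj`, `label`,
#'   and the interaction coefficient (`lfc_state`, `padj_state`).
#' @export
chromatin_association <- function(char_counts, rna_counts, char_info,
                                  rna_info, fdr = 0.05, min_fold = 3,
                                  min_total = 10, sf_min_total = 50) {
  genes <- intersect(rownames(char_counts), rownames(rna_counts))
  counts <- cbind(char_counts[genes, , drop = FALSE],
                  rna_counts[genes, , drop = FALSE])
  info <- bind_rows(
    mutate(char_info, sequencing = "charseq"),
    mutate(rna_info, sequencing = "rnaseq")
  )
  colnames(counts) <- info$sample_id
  info$sequencing <- factor(info$sequencing,
                            levels = c("rnaseq", "charseq"))
  keep <- rowSums(counts) >= min_total
  counts <- counts[keep, , drop = FALSE]
  sf <- estimate_size_factors(counts,
                              row_subset = rowSums(counts) >= sf_min_total)

  states <- sort(unique(info$cell))
  out <- list()
  for (s in states) {
    cd <- info
    cd$cell <- stats::relevel(factor(cd$cell), ref = s)
    main <- nb_glm_test(counts, cd, ~ cell + sequencing + cell:sequencing,
                        "sequencingcharseq", size_factors = sf)
    other <- setdiff(levels(cd$cell), s)[1]
    inter <- nb_glm_test(counts, cd, ~ cell + sequencing + cell:sequencing,
                         paste0("cell", other, ":sequencingcharseq"),
                         size_factors = sf)
    out[[s]] <- tibble(
      gene_id = rownames(counts), state = s,
      score = main$shrunken_lfc, lfc_raw = main$lfc, padj = main$padj,
      lfc_state = inter$shrunken_lfc, padj_state = inter$padj
    )
  }
  res <- bind_rows(out)
  mutate(res, label = dplyr::case_when(
    !is.na(.data$padj) & .data$padj < fdr &
      .data$score > log2(min_fold) ~ "enriched",
    !is.na(.data$padj) & .data$padj < fdr &
      .data$score < -log2(min_fold) ~ "depleted",
    TRUE ~ "none"
  ))
}
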
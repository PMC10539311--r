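#' Per-RNA far/near contact counts for delocalization scoring
#'
#' In `trans` mode, counts for each RNA (per sample) the total number of
#' contacts `N` and the number of contacts on chromosomes other than the
#' RNA's source chromosome (`N_far`). In `cis` mode, only contacts on the
#' source chromosome are considered; they are partitioned by the absolute
#' travel distance |dna_pos - rna_pos| into near (<= D) and far (> D),
#' with the boundary |delta| = D assigned to near, and `N = N_near +
#' N_far`.
#'
#' @param records Contact-record tibble.
#' @param gene_models Gene-model tibble (source chromosome and class per
#'   RNA). RNAs absent from it are excluded with a message.
#' @param mode `"trans"` or `"cis"`.
#' @param D Travel-distance threshold in bp for cis mode (default 1 Mb;
#'   10 Mb is a common alternative for chromosome-scale spreading).
#' @return Tibble with one row per (RNA, sample): `gene_id`, `sample_id`,
#'   `chrom`, `rna_class`, `N`, `N_far`, `lnN`, `mode`, `D`.
#' @export
compute_far_counts <- function(records, gene_models, mode = c("trans", "cis"),
                               D = 1e6) {
  mode <- match.arg(mode)
  known <- records$rna_gene_id %in% gene_models$gene_id
  if (any(!known)) {
    message(sum(!known), " record(s) from RNAs absent from gene models ",
            "excluded from delocalization input")
    records <- records[known, , drop = FALSE]
  }
  gi <- match(records$rna_gene_id, gene_models$gene_id)
  src_chrom <- gene_models$chrom[gi]
  if (mode == "trans") {
    tab <- tibble(
      gene_id = records$rna_gene_id, sample_id = records$sample_id,
      far = records$dna_chrom != src_chrom
    ) |>
      group_by(.data$gene_id, .data$sample_id) |>
      summarise(N = n(), N_far = sum(.data$far), .groups = "drop")
  } else {
    cis <- records$dna_chrom == src_chrom
    delta <- abs(records$dna_pos - records$rna_pos)
    tab <- tibble(
      gene_id = records$rna_gene_id[cis], sample_id = records$sample_id[cis],
      far = delta[cis] > D
    ) |>
      group_by(.data$gene_id, .data$sample_id) |>
      summarise(N = n(), N_far = sum(.data$far), .groups = "drop")
  }
  gi2 <- match(tab$gene_id, gene_models$gene_id)
  mutate(tab,
         chrom = gene_models$chrom[gi2],
         rna_class = gene_models$rna_class[gi2],
         lnN = log(.data$N), mode = mode, D = D) |>
    select("gene_id", "sample_id", "chrom", "rna_class", "N", "N_far",
           "lnN", "mode", "D")
}

#' Raw delocalization score (log2 contact-density ratio)
#'
#' The raw score compares the contact density far from the RNA locus with
#' the density near it. In trans mode the densities are `N_far` over the
#' summed length of the trans chromosomes versus `N - N_far` over the
#' source chromosome. In cis mode the near window is the +-D interval
#' around the TSS (clipped at the chromosome ends) and the far length is
#' the remainder of the source chromosome.
#'
#' @param far_counts Tibble from [compute_far_counts()].
#' @param genome A [genome_layout()].
#' @param gene_models Gene-model tibble (needed in cis mode for the TSS).
#' @return `far_counts` with columns `raw_score` (log2; `NA` when either
#'   density is zero) added.
#' @export
raw_score <- function(far_counts, genome, gene_models = NULL) {
  mode <- far_counts$mode[1]
  L_total <- genome_length(genome)
  if (mode == "trans") {
    L_near <- chrom_length(genome, far_counts$chrom)
    L_far <- L_total - L_near
  } else {
    if (is.null(gene_models)) stop("gene_models required in cis mode")
    gi <- match(far_counts$gene_id, gene_models$gene_id)
    tss <- gene_models$tss[gi]
    len <- chrom_length(genome, far_counts$chrom)
    D <- far_counts$D
    L_near <- pmin(tss + D, len) - pmax(tss - D, 0)
    L_far <- len - L_near
  }
  n_near <- far_counts$N - far_counts$N_far
  score <- log2((far_counts$N_far / L_far) / (n_near / L_near))
  bad <- far_counts$N_far == 0 | n_near == 0 | L_far <= 0
  if (any(bad)) {
    message(sum(bad), " RNA(s) with a zero far or near density excluded ",
            "from raw-score ranking")
    score[bad] <- NA_real_
  }
  mutate(far_counts, raw_score = score)
}

# Beta-binomial log-likelihood with the intraclass-correlation
# parameterization: shape1 + shape2 = 1/gamma - 1, so that
# var(k | n) = n pi (1-pi) (1 + (n-1) gamma).
ll_betabin <- function(k, n, pi, gamma) {
  if (gamma < 1e-12) {
    return(stats::dbinom(k, n, pi, log = TRUE))
  }
  s <- 1 / gamma - 1
  a <- pi * s
  b <- (1 - pi) * s
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

#' Fit the beta-binomial regression null of far-contact rates
#'
#' Models the per-RNA far-contact count as beta-binomial given the RNA's
#' total count, with a logit-linear mean: one intercept per source
#' chromosome (no global intercept) plus a log-total-count covariate, and
#' a single overdispersion `gamma` shared across RNAs. The model is
#' trained on a reference class (mRNAs by default), whose members are
#' assumed to have no specific far-targeting, and RNAs with fewer than
#' `min_total` contacts are removed before fitting. Maximum likelihood is
#' obtained by quasi-Newton optimization with `gamma` parameterized on
#' the logit scale; initial values come from a binomial GLM plus a
#' method-of-moments overdispersion estimate, with random restarts on
#' failure.
#'
#' @param inputs Tibble from [compute_far_counts()] (one sample).
#' @param training_class RNA class used for training (default `"mRNA"`).
#' @param min_total Minimum total count for a training RNA (default 50).
#' @param max_restarts Random restarts attempted after a failed fit.
#' @param include_expr Include the log-total-count covariate (default
#'   `TRUE`); with `FALSE` the mean is chromosome intercepts only.
#' @return An object of class `betabin_glm_fit` with elements `eta_chr`
#'   (named chromosome intercepts), `eta_expr`, `gamma`, standard errors,
#'   `logLik`, `converged`, and bookkeeping fields.
#' @export
fit_betabin_glm <- function(inputs, training_class = "mRNA", min_total = 50,
                            max_restarts = 3, include_expr = TRUE) {
  chrom_levels <- sort(unique(inputs$chrom))
  tr <- filter(inputs, .data$rna_class == training_class,
               .data$N >= min_total)
  if (nrow(tr) < 10) {
    stop("too few training RNAs after the min_total filter (",
         nrow(tr), ")")
  }
  tr_chroms <- sort(unique(tr$chrom))
  missing_chroms <- setdiff(chrom_levels, tr_chroms)
  # chromosome indicator columns built directly (a one-level factor has
  # no contrasts), plus the optional log-count covariate
  X <- 1 * outer(tr$chrom, tr_chroms, "==")
  colnames(X) <- tr_chroms
  if (include_expr) X <- cbind(X, lnN = tr$lnN)
  k <- tr$N_far
  n <- tr$N
  p_eta <- ncol(X)

  nll <- function(par) {
    eta <- drop(X %*% par[seq_len(p_eta)])
    pi <- plogis(eta)
    pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
    gamma <- plogis(par[p_eta + 1])
    v <- -sum(ll_betabin(k, n, pi, gamma))
    if (!is.finite(v)) v <- 1e10
    v
  }

  bin0 <- glm.fit(X, cbind(k, n - k), family = binomial())
  mu0 <- plogis(drop(X %*% bin0$coefficients))
  phi <- sum((k - n * mu0)^2 / (n * mu0 * (1 - mu0))) /
    max(1, nrow(tr) - p_eta)
  gamma0 <- min(max((phi - 1) / (mean(n) - 1), 1e-4), 0.3)
  par0 <- c(bin0$coefficients, qlogis(gamma0))

  fit <- NULL
  for (attempt in 0:max_restarts) {
    par_try <- if (attempt == 0) par0 else par0 + rnorm(length(par0), 0, 0.3)
    res <- tryCatch(
      optim(par_try, nll, method = "BFGS",
            control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(res) && res$convergence == 0 && is.finite(res$value)) {
      fit <- res
      break
    }
  }
  if (is.null(fit)) {
    stop("beta-binomial GLM did not converge after ", max_restarts,
         " restarts; n_train=", nrow(tr),
         ", init gamma=", signif(gamma0, 3))
  }

  H <- tryCatch(optimHess(fit$par, nll), error = function(e) NULL)
  ses <- rep(NA_real_, length(fit$par))
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)
      ses[d > 0] <- sqrt(d[d > 0])
    }
  }

  eta_chr <- setNames(unname(fit$par[seq_along(tr_chroms)]), tr_chroms)
  se_chr <- setNames(ses[seq_along(tr_chroms)], tr_chroms)
  if (length(missing_chroms) > 0) {
    warning("no training RNAs on ", paste(missing_chroms, collapse = ", "),
            "; their intercepts set to the mean of fitted intercepts")
    eta_chr[missing_chroms] <- mean(fit$par[seq_along(tr_chroms)])
    se_chr[missing_chroms] <- NA_real_
    eta_chr <- eta_chr[chrom_levels]
    se_chr <- se_chr[chrom_levels]
  }
  gamma <- unname(plogis(fit$par[p_eta + 1]))
  structure(
    list(
      eta_chr = eta_chr,
      eta_expr = if (include_expr) unname(fit$par[p_eta]) else 0,
      gamma = gamma,
      se_eta_chr = se_chr,
      se_eta_expr = if (include_expr) unname(ses[p_eta]) else NA_real_,
      se_gamma = unname(ses[p_eta + 1]) * gamma * (1 - gamma),
      logLik = -fit$value,
      converged = TRUE,
      n_train = nrow(tr),
      training_class = training_class,
      min_total = min_total,
      chrom_levels = names(eta_chr),
      imputed_chroms = missing_chroms,
      mode = inputs$mode[1]
    ),
    class = "betabin_glm_fit"
  )
}

#' @export
print.betabin_glm_fit <- function(x, ...) {
  cat("<betabin_glm_fit> ", x$mode, " mode, ", x$n_train, " training ",
      x$training_class, "s\n", sep = "")
  cat("  eta_chr: ", paste(sprintf("%s=%.3f", names(x$eta_chr), x$eta_chr),
                           collapse = ", "), "\n", sep = "")
  cat(sprintf("  eta_expr = %.4f, gamma = %.4g\n", x$eta_expr, x$gamma))
  invisible(x)
}

#' Model-predicted far-contact rate for given covariates
#' @param fit A `betabin_glm_fit`.
#' @param chrom,lnN Covariate vectors.
#' @return Vector of predicted rates on the probability scale.
#' @export
predict_pi_model <- function(fit, chrom, lnN) {
  eta <- fit$eta_chr[chrom]
  if (anyNA(eta)) {
    stop("chromosome not covered by the fit: ",
         paste(unique(chrom[is.na(eta)]), collapse = ", "))
  }
  unname(plogis(eta + fit$eta_expr * lnN))
}

#' Empirical-Bayes posterior far-contact rate
#'
#' Uses the fitted beta-binomial null as a conjugate prior: the prior is
#' Beta with mean equal to the model-predicted rate and total
#' concentration `1/gamma - 1` (the beta-binomial variance identity), and
#' the posterior adds the observed far / near counts. The posterior mean
#' is a shrinkage estimate lying between the model prediction and the
#' empirical proportion.
#'
#' @param fit A `betabin_glm_fit`.
#' @param inputs Tibble from [compute_far_counts()].
#' @return `inputs` with columns `pi_model`, `prior_shape1`,
#'   `prior_shape2`, `post_shape1`, `post_shape2`, `pi_post` added.
#' @export
posterior_rate <- function(fit, inputs) {
  pi_model <- predict_pi_model(fit, inputs$chrom, inputs$lnN)
  if (fit$gamma < 1e-12) {
    warning("gamma is zero; using a unit pseudo-count prior around the ",
            "model prediction")
    s <- 1
  } else {
    s <- 1 / fit$gamma - 1
  }
  a0 <- pi_model * s
  b0 <- (1 - pi_model) * s
  mutate(inputs,
         pi_model = pi_model,
         prior_shape1 = a0, prior_shape2 = b0,
         post_shape1 = a0 + .data$N_far,
         post_shape2 = b0 + .data$N - .data$N_far,
         pi_post = .data$post_shape1 /
           (.data$post_shape1 + .data$post_shape2))
}

#' Calibrated delocalization score
#'
#' The calibrated score is the shrinkage estimate of the far-contact rate
#' expressed relative to the model prediction on the log-odds scale:
#' `delta = (logit(pi_post) - logit(pi_model)) / ln 2` in log2 units by
#' default (a log2 odds ratio), or natural-log units via `base = "ln"`.
#' Rates at the boundary are clipped to `[1e-12, 1 - 1e-12]`.
#'
#' @param posterior Tibble from [posterior_rate()].
#' @param base `"log2"` (default) or `"ln"`.
#' @return `posterior` with a `delta` column added.
#' @export
delocalization_score <- function(posterior, base = c("log2", "ln")) {
  base <- match.arg(base)
  clip <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  d <- qlogis(clip(posterior$pi_post)) - qlogis(clip(posterior$pi_model))
  if (base == "log2") d <- d / log(2)
  mutate(posterior, delta = d)
}

#' Exceedance probability of one Beta variable over another
#'
#' Computes P(X > Y) for independent X ~ Beta(a1, b1) and
#' Y ~ Beta(a2, b2) by deterministic quadrature of the integral of
#' f_X(x) F_Y(x), with a Monte-Carlo fallback (1e6 draws, flagged by a
#' warning) if the quadrature fails to converge.
#'
#' @param a1,b1 Shape parameters of X (vectors recycle).
#' @param a2,b2 Shape parameters of Y.
#' @param abs_tol Absolute tolerance of the quadrature.
#' @return Vector of probabilities in [0, 1].
#' @export
beta_exceedance <- function(a1, b1, a2, b2, abs_tol = 1e-8) {
  n <- max(length(a1), length(b1), length(a2), length(b2))
  a1 <- rep_len(a1, n); b1 <- rep_len(b1, n)
  a2 <- rep_len(a2, n); b2 <- rep_len(b2, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    f <- function(x) dbeta(x, a1[i], b1[i]) * pbeta(x, a2[i], b2[i])
    # integrate over the central mass of X to keep the integrand tame
    lo <- qbeta(1e-12, a1[i], b1[i])
    hi <- qbeta(1 - 1e-12, a1[i], b1[i])
    res <- tryCatch(
      integrate(f, lo, hi, abs.tol = abs_tol, subdivisions = 500L),
      error = function(e) NULL
    )
    if (!is.null(res) && res$message == "OK") {
      out[i] <- min(max(res$value, 0), 1)
    } else {
      warning("quadrature failed for parameter set ", i,
              "; falling back to Monte Carlo")
      x <- rbeta(1e6, a1[i], b1[i])
      y <- rbeta(1e6, a2[i], b2[i])
      out[i] <- mean(x > y)
    }
  }
  out
}

#' Tail probability for delocalization calling
#'
#' For each RNA, compares a draw from its posterior far-contact rate with
#' a draw from the prior implied by the null model at the same
#' covariates. `p_deloc = P(prior draw >= posterior draw)` is small when
#' the RNA makes more far contacts than the null predicts (delocalized);
#' its complement `p_ultra = P(posterior draw > prior draw)` is small for
#' ultralocalized RNAs. Under null data the two are uniform, so either
#' tail cuts off the expected 5% at the 0.05 level.
#'
#' @param posterior Tibble from [posterior_rate()].
#' @return `posterior` with columns `p_deloc` and `p_ultra` added.
#' @export
tail_probability <- function(posterior) {
  exc <- beta_exceedance(posterior$post_shape1, posterior$post_shape2,
                         posterior$prior_shape1, posterior$prior_shape2)
  mutate(posterior, p_deloc = 1 - exc, p_ultra = exc)
}

#' Combine replicate tail probabilities and classify RNAs
#'
#' Within each cell state, per-replicate tail probabilities are combined
#' with Fisher's method (statistic -2 sum log p, chi-square with
#' 2 x replicates df), separately for the delocalized side (`p_deloc`)
#' and the ultralocalized side (`p_ultra`). Benjamini-Hochberg adjustment
#' is applied across RNAs within each (state, side) family, and an RNA is
#' classified delocalized or ultralocalized when the corresponding
#' adjusted p-value is below `fdr`. The calibrated score is summarized as
#' the arithmetic mean over replicates.
#'
#' @param per_replicate Tibble with columns `gene_id`, `state`,
#'   `sample_id`, `delta`, `p_deloc`, `p_ultra` (one row per RNA per
#'   replicate).
#' @param fdr Nominal false-discovery rate (default 0.05).
#' @return Tibble with one row per (RNA, state): mean `delta`, combined
#'   and adjusted p-values for both sides, and `category` in
#'   `delocalized` / `ultralocalized` / `neither`.
#' @export
combine_and_classify <- function(per_replicate, fdr = 0.05) {
  fisher_p <- function(p) {
    p <- pmax(p, 1e-300)
    stat <- -2 * sum(log(p))
    pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
  }
  out <- per_replicate |>
    group_by(.data$gene_id, .data$state) |>
    summarise(
      n_rep = n(),
      delta = mean(.data$delta),
      p_deloc_comb = fisher_p(.data$p_deloc),
      p_ultra_comb = fisher_p(.data$p_ultra),
      .groups = "drop"
    ) |>
    group_by(.data$state) |>
    mutate(
      p_deloc_adj = p.adjust(.data$p_deloc_comb, method = "BH"),
      p_ultra_adj = p.adjust(.data$p_ultra_comb, method = "BH")
    ) |>
    ungroup()
  mutate(out, category = dplyr::case_when(
    .data$p_deloc_adj < fdr ~ "delocalized",
    .data$p_ultra_adj < fdr ~ "ultralocalized",
    TRUE ~ "neither"
  ))
}

#' End-to-end delocalization scoring pipeline
#'
#' Runs, per sample: far-count computation, beta-binomial null fitting on
#' the training class, empirical-Bayes posterior rates, calibrated
#' scores, and tail probabilities; then combines replicates within each
#' cell state and classifies RNAs.
#'
#' @param records Contact-record tibble covering all samples.
#' @param gene_models Gene-model tibble.
#' @param genome A [genome_layout()].
#' @param sample_info Tibble with columns `sample_id`, `state`,
#'   `replicate`.
#' @param mode `"trans"` or `"cis"`.
#' @param D Cis travel-distance threshold (bp).
#' @param fdr Nominal FDR for classification.
#' @param training_class,min_total Passed to [fit_betabin_glm()].
#' @return List with `per_sample` (per-replicate scores), `per_state`
#'   (classified results), and `fits` (one `betabin_glm_fit` per sample).
#' @export
score_delocalization <- function(records, gene_models, genome, sample_info,
                                 mode = c("trans", "cis"), D = 1e6,
                                 fdr = 0.05, training_class = "mRNA",
                                 min_total = 50) {
  mode <- match.arg(mode)
  fits <- list()
  per_sample <- list()
  for (s in sample_info$sample_id) {
    rec_s <- records[records$sample_id == s, , drop = FALSE]
    fc <- compute_far_counts(rec_s, gene_models, mode = mode, D = D)
    fc <- filter(fc, .data$N >= min_total)
    fit <- fit_betabin_glm(fc, training_class = training_class,
                           min_total = min_total)
    sc <- fc |>
      posterior_rate(fit = fit) |>
      delocalization_score() |>
      tail_probability()
    sc <- raw_score(sc, genome, gene_models)
    fits[[s]] <- fit
    per_sample[[s]] <- sc
  }
  per_sample <- bind_rows(per_sample)
  per_sample <- left_join(per_sample,
                          select(sample_info, "sample_id", "state",
                                 "replicate"),
                          by = "sample_id")
  per_state <- combine_and_classify(per_sample, fdr = fdr)
  list(per_sample = per_sample, per_state = per_state, fits = fits)
}
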
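test_that("far counts match a per-record classification oracle", {
  g <- tiny_genome()
  gm <- gene_models(c("gA", "gB", "gC"), c("chr1", "chr2", "chr1"),
                    c("+", "-", "+"), c(0, 0, 100), c(1000, 1000, 2000),
                    c("mRNA", "mRNA", "lncRNA"), genome = g)
  rec <- make_records(100, seed = 5)

  fc <- compute_far_counts(rec, gm, mode = "trans")
  for (r in seq_len(nrow(fc))) {
    sub <- rec[rec$rna_gene_id == fc$gene_id[r], ]
    src <- gm$chrom[gm$gene_id == fc$gene_id[r]]
    expect_equal(fc$N[r], nrow(sub))
    expect_equal(fc$N_far[r], sum(sub$dna_chrom != src))
  }

  fc_cis <- compute_far_counts(rec, gm, mode = "cis", D = 5e5)
  for (r in seq_len(nrow(fc_cis))) {
    sub <- rec[rec$rna_gene_id == fc_cis$gene_id[r], ]
    src <- gm$chrom[gm$gene_id == fc_cis$gene_id[r]]
    sub <- sub[sub$dna_chrom == src, ]
    d <- abs(sub$dna_pos - sub$rna_pos)
    expect_equal(fc_cis$N[r], nrow(sub))
    expect_equal(fc_cis$N_far[r], sum(d > 5e5))  # boundary goes to near
  }

  # all contacts on the source chromosome -> N_far = 0 in trans mode
  rec2 <- make_records(10)
  rec2$rna_gene_id <- "gA"
  rec2$dna_chrom <- "chr1"
  expect_equal(compute_far_counts(rec2, gm, mode = "trans")$N_far, 0)

  # explicit near/far split around the threshold
  rec3 <- make_records(2)
  rec3$rna_gene_id <- "gB"
  rec3$dna_chrom <- "chr2"
  rec3$rna_pos <- c(0, 0)
  rec3$dna_pos <- c(1e4, 1.9e6)
  out <- compute_far_counts(rec3, gm, mode = "cis", D = 1e6)
  expect_equal(out$N - out$N_far, 1)
  expect_equal(out$N_far, 1)

  # RNAs absent from the gene models are excluded with a message
  rec4 <- rec
  rec4$rna_gene_id[1:3] <- "unknown"
  expect_message(compute_far_counts(rec4, gm, mode = "trans"), "excluded")
})

test_that("raw score reproduces direct density-ratio arithmetic", {
  g <- genome_layout(c("chrA", "chrB"), c(1e8, 9e8))
  fc <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), sample_id = "s", chrom = "chrA",
    rna_class = "mRNA", N = c(100, 110, 20), N_far = c(10, 20, 18),
    lnN = log(c(100, 110, 20)), mode = "trans", D = 1e6
  )
  rs <- raw_score(fc, g)
  expect_equal(rs$raw_score[1], -6.33985, tolerance = 1e-5)
  # doubling N_far at fixed N_cis raises the score by exactly 1
  expect_equal(rs$raw_score[2] - rs$raw_score[1], 1)
  # equal densities -> 0  (N_far/L_far == N_cis/L_cis)
  expect_equal(rs$raw_score[3], 0)
  # zero numerator -> NA with a message
  fc0 <- dplyr::mutate(fc[1, ], N_far = 0)
  expect_message(rs0 <- raw_score(fc0, g), "zero")
  expect_true(is.na(rs0$raw_score))
})

test_that("beta-binomial GLM reduces to the pooled binomial MLE", {
  set.seed(8)
  n <- 200
  N <- sample(100:1000, n, replace = TRUE)
  k <- rbinom(n, N, 0.3)
  inputs <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n), sample_id = "s", chrom = "chr1",
    rna_class = "mRNA", N = N, N_far = k, lnN = log(N),
    mode = "trans", D = NA
  )
  fit <- fit_betabin_glm(inputs, include_expr = FALSE)
  expect_true(fit$converged)
  expect_lt(fit$gamma, 5e-3)  # binomial data: gamma near 0
  expect_equal(plogis(fit$eta_chr[["chr1"]]), sum(k) / sum(N),
               tolerance = 2e-3)
})

test_that("training filter removes RNAs below the minimum total count", {
  set.seed(9)
  n <- 120
  N <- c(rep(49, 20), sample(200:2000, 100, replace = TRUE))
  k <- rbinom(n, N, 0.35)
  inputs <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n), sample_id = "s", chrom = "chr1",
    rna_class = "mRNA", N = N, N_far = k, lnN = log(N),
    mode = "trans", D = NA
  )
  fit <- fit_betabin_glm(inputs, min_total = 50)
  expect_equal(fit$n_train, 100)
})

test_that("beta-binomial GLM agrees with an independent TMB fit", {
  skip_if_not_installed("glmmTMB")
  fit0 <- make_fit(eta_chr = stats::qlogis(c(chr1 = 0.25, chr2 = 0.45)),
                   eta_expr = 0.08, gamma = 0.05)
  cov <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 300),
    N = round(exp(runif(600, log(100), log(5000))))
  )
  sim <- simulate_null_glm_counts(fit0, cov, seed = 21)
  fit <- fit_betabin_glm(sim)

  dat <- data.frame(k = sim$N_far, n = sim$N, chrom = factor(sim$chrom),
                    lnN = sim$lnN)
  tmb <- suppressWarnings(glmmTMB::glmmTMB(
    cbind(k, n - k) ~ 0 + chrom + lnN, data = dat,
    family = glmmTMB::betabinomial()))
  tmb_coef <- glmmTMB::fixef(tmb)$cond
  # glmmTMB dispersion phi relates to the intraclass gamma as 1/(phi+1)
  tmb_gamma <- 1 / (glmmTMB::sigma(tmb) + 1)
  expect_equal(unname(fit$eta_chr), unname(tmb_coef[1:2]), tolerance = 1e-2)
  expect_equal(fit$eta_expr, unname(tmb_coef[3]), tolerance = 1e-2)
  expect_equal(fit$gamma, tmb_gamma, tolerance = 0.1)
})

test_that("posterior rate follows the conjugate closed form", {
  fit <- make_fit(eta_chr = c(chr1 = stats::qlogis(0.2)), eta_expr = 0,
                  gamma = 0.1)
  inp <- tibble::tibble(
    gene_id = "g", sample_id = "s", chrom = "chr1", rna_class = "x",
    N = 10, N_far = 5, lnN = log(10), mode = "trans", D = NA
  )
  post <- posterior_rate(fit, inp)
  # prior: mean 0.2, concentration 1/0.1 - 1 = 9 -> Beta(1.8, 7.2)
  expect_equal(post$prior_shape1, 1.8)
  expect_equal(post$prior_shape2, 7.2)
  # with a Beta(2, 8) prior, N = 10, k = 5 -> Beta(7, 13), mean 0.35
  fit2 <- make_fit(eta_chr = c(chr1 = stats::qlogis(0.2)), eta_expr = 0,
                   gamma = 1 / 11)  # concentration 10 -> Beta(2, 8)
  post2 <- posterior_rate(fit2, inp)
  expect_equal(post2$post_shape1, 7)
  expect_equal(post2$post_shape2, 13)
  expect_equal(post2$pi_post, 0.35)
  # N = 0 -> posterior equals prior
  inp0 <- dplyr::mutate(inp, N = 0, N_far = 0, lnN = 0)
  post0 <- posterior_rate(fit2, inp0)
  expect_equal(post0$post_shape1, post0$prior_shape1)
  expect_equal(post0$pi_post, post0$pi_model)
})

test_that("pi_post is a convex combination, monotone in the far count", {
  fit <- make_fit(gamma = 0.05)
  for (N in c(5, 50, 500)) {
    ks <- 0:N
    inp <- tibble::tibble(
      gene_id = sprintf("g%d", ks), sample_id = "s", chrom = "chr1",
      rna_class = "x", N = N, N_far = ks, lnN = log(N),
      mode = "trans", D = NA
    )
    post <- posterior_rate(fit, inp)
    lo <- pmin(post$pi_model, post$N_far / post$N)
    hi <- pmax(post$pi_model, post$N_far / post$N)
    expect_true(all(post$pi_post >= lo - 1e-12 & post$pi_post <= hi + 1e-12))
    expect_true(all(diff(post$pi_post) > 0))
  }
})

test_that("calibrated score is the log2 odds ratio of posterior vs model", {
  post <- tibble::tibble(pi_model = c(0.2, 0.2, 0.2),
                         pi_post = c(0.2, 1 / 3, 0.35))
  # odds 0.25 doubled is odds 0.5 = rate 1/3
  d <- delocalization_score(post)$delta
  expect_equal(d[1], 0)
  expect_equal(d[2], 1)
  expect_equal(d[3], 1.106915, tolerance = 1e-5)
  d_ln <- delocalization_score(post, base = "ln")$delta
  expect_equal(d_ln, d * log(2))
})

test_that("beta exceedance quadrature matches symmetry, dominance and MC", {
  expect_equal(beta_exceedance(3, 7, 3, 7), 0.5, tolerance = 1e-7)
  expect_gt(beta_exceedance(500, 1, 1, 500), 1 - 1e-6)
  expect_lt(beta_exceedance(1, 500, 500, 1), 1e-6)
  # Monte-Carlo oracle on random parameter sets
  set.seed(14)
  n_mc <- 2e5
  for (i in 1:20) {
    a1 <- runif(1, 0.5, 50); b1 <- runif(1, 0.5, 50)
    a2 <- runif(1, 0.5, 50); b2 <- runif(1, 0.5, 50)
    q <- beta_exceedance(a1, b1, a2, b2)
    x <- rbeta(n_mc, a1, b1); y <- rbeta(n_mc, a2, b2)
    mc <- mean(x > y)
    se <- sqrt(mc * (1 - mc) / n_mc)
    expect_lt(abs(q - mc), 3 * max(se, 1e-5))
  }
})

test_that("tail probabilities are complementary and directionally correct", {
  fit <- make_fit(eta_chr = c(chr1 = stats::qlogis(0.3)), gamma = 0.02)
  inp <- tibble::tibble(
    gene_id = c("high", "null", "low"), sample_id = "s", chrom = "chr1",
    rna_class = "x", N = c(1000, 1000, 1000), N_far = c(900, 300, 10),
    lnN = log(1000), mode = "trans", D = NA
  )
  tp <- tail_probability(posterior_rate(fit, inp))
  expect_equal(tp$p_deloc + tp$p_ultra, rep(1, 3))
  expect_lt(tp$p_deloc[1], 1e-4)   # strongly delocalized
  expect_gt(tp$p_deloc[2], 0.05)   # consistent with the null
  expect_lt(tp$p_ultra[3], 1e-4)   # strongly ultralocalized
})

test_that("Fisher combination and BH classification behave as expected", {
  fisher_two <- function(p) {
    per <- tibble::tibble(
      gene_id = "g", state = "ES", sample_id = c("r1", "r2"),
      delta = c(1, 2), p_deloc = p, p_ultra = 1 - p
    )
    combine_and_classify(per)
  }
  flat <- fisher_two(c(1, 1))
  expect_equal(flat$p_deloc_comb, 1)
  expect_equal(flat$delta, 1.5)  # arithmetic mean over replicates

  mid <- fisher_two(c(0.05, 0.05))
  expect_equal(mid$p_deloc_comb, 0.01747866, tolerance = 1e-6)

  # adjusted p below the FDR threshold -> delocalized
  expect_equal(mid$category, "delocalized")
  expect_equal(fisher_two(c(0.5, 0.6))$category, "neither")
  expect_equal(fisher_two(c(0.99, 0.999))$category, "ultralocalized")

  # p = 0 is floored, not -Inf
  expect_true(is.finite(fisher_two(c(0, 0))$p_deloc_comb))
})

test_that("null simulator reproduces the beta-binomial variance law", {
  # binomial limit: gamma -> 0, pi = 0.5, var/N ~= 0.25
  fit0 <- make_fit(eta_chr = c(chr1 = 0), eta_expr = 0, gamma = 0)
  cov <- tibble::tibble(chrom = rep("chr1", 2e4), N = 1000)
  expect_warning(sim0 <- simulate_null_glm_counts(fit0, cov, seed = 3),
                 "binomial")
  expect_equal(var(sim0$N_far) / 1000, 0.25, tolerance = 0.05)

  # overdispersed: var = N pi (1-pi) (1 + (N-1) gamma), within 2%
  fit1 <- make_fit(eta_chr = c(chr1 = stats::qlogis(0.2)), eta_expr = 0,
                   gamma = 0.1)
  cov1 <- tibble::tibble(chrom = rep("chr1", 1e5), N = 100)
  sim1 <- simulate_null_glm_counts(fit1, cov1, seed = 4)
  v_expect <- 0.2 * 0.8 * 100 * (1 + 99 * 0.1)
  expect_equal(var(sim1$N_far), v_expect, tolerance = 0.02)

  # seed determinism
  expect_identical(simulate_null_glm_counts(fit1, cov1[1:100, ], seed = 5),
                   simulate_null_glm_counts(fit1, cov1[1:100, ], seed = 5))
})
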
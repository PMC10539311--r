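library(Matrix)

mk_map <- function(m, scheme, id = "s") {
  contact_matrix(Matrix(m, sparse = TRUE), scheme, sample_id = id)
}

test_that("interaction tables apply the count filter on chosen samples", {
  g <- genome_layout("chr1", 4e5)
  scheme <- bin_scheme_uniform(g, 1e5)
  rn <- c("rA", "rB")
  base <- function(v) {
    m <- matrix(0, 2, 4, dimnames = list(rn, NULL))
    m[1, 1] <- v
    m
  }
  si <- tibble::tibble(sample_id = paste0("s", 1:4),
                       cell = c("ES", "ES", "DE", "DE"))
  # row counts 12, 3, 10, 0 across samples -> retained (>=10 in >=2)
  maps <- list(s1 = mk_map(base(12), scheme), s2 = mk_map(base(3), scheme),
               s3 = mk_map(base(10), scheme), s4 = mk_map(base(0), scheme))
  tab <- build_interaction_table(maps, si)
  expect_equal(nrow(tab$rows), 1)
  expect_equal(unname(tab$counts[1, ]), c(12, 3, 10, 0))

  # row counts 9, 9, 9, 9 -> excluded
  maps2 <- lapply(1:4, function(i) mk_map(base(9), scheme))
  names(maps2) <- si$sample_id
  tab2 <- build_interaction_table(maps2, si)
  expect_equal(nrow(tab2$rows), 0)
  expect_equal(tab2$n_excluded, 1)

  # filter evaluated on a subset of samples only
  tab3 <- build_interaction_table(maps, si, filter_on = c("s2", "s4"))
  expect_equal(nrow(tab3$rows), 0)

  # empty maps -> empty table
  maps0 <- lapply(1:4, function(i) mk_map(base(0), scheme))
  names(maps0) <- si$sample_id
  expect_equal(nrow(build_interaction_table(maps0, si)$rows), 0)
})

test_that("expression-only maps are row-constant at the RNA total", {
  g <- genome_layout("chr1", 3e5)
  scheme <- bin_scheme_uniform(g, 1e5)
  m <- matrix(c(3, 0, 4, 0, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("r1", "r2"), NULL))
  em <- expression_only_map(mk_map(m, scheme))
  expect_equal(as.numeric(em$counts[1, ]), rep(7, 3))
  expect_equal(as.numeric(em$counts[2, ]), rep(0, 3))

  # property: row max equals row min for random matrices
  set.seed(42)
  for (i in 1:20) {
    mm <- matrix(rpois(15, 3), 5, 3,
                 dimnames = list(paste0("g", 1:5), NULL))
    e <- expression_only_map(mk_map(mm, scheme))
    expect_equal(apply(as.matrix(e$counts), 1, max),
                 apply(as.matrix(e$counts), 1, min))
  }
})

test_that("size factors follow median-of-ratios arithmetic", {
  tab <- matrix(c(2, 4, 3, 6, 10, 20), 3, 2, byrow = TRUE)
  sf <- estimate_size_factors(tab)
  expect_equal(sf, c(0.7071068, 1.4142136), tolerance = 1e-6)

  expect_equal(estimate_size_factors(cbind(c(5, 9), c(5, 9))), c(1, 1))

  # scaling one column scales its factor (before the geometric rescale)
  tab3 <- tab
  tab3[, 2] <- tab3[, 2] * 3
  sf3 <- estimate_size_factors(tab3)
  expect_equal(sf3[2] / sf3[1], 3 * sf[2] / sf[1], tolerance = 1e-9)

  # invariant to row permutation
  expect_equal(estimate_size_factors(tab[c(3, 1, 2), ]), sf)

  expect_equal(exp(mean(log(sf))), 1)
  expect_error(estimate_size_factors(matrix(c(0, 1, 2, 0), 2)),
               "no all-positive")
})

test_that("the NB engine recovers planted fold changes, nulls stay flat", {
  cd <- tibble::tibble(cell = c("ES", "ES", "DE", "DE"))
  # identical counts -> LFC 0
  eq <- matrix(5, 4, 4)
  res_eq <- nb_glm_test(eq, cd, ~ cell, "cellES", size_factors = rep(1, 4))
  expect_equal(res_eq$lfc, rep(0, 4), tolerance = 1e-9)

  # planted 4-fold rows at mean 100: median raw LFC in [1.8, 2.2]
  set.seed(6)
  counts <- cbind(matrix(rnbinom(2000, mu = 400, size = 10), 1000, 2),
                  matrix(rnbinom(2000, mu = 100, size = 10), 1000, 2))
  res <- nb_glm_test(counts, cd, ~ cell, "cellES",
                     size_factors = rep(1, 4))
  expect_gt(median(res$lfc), 1.8)
  expect_lt(median(res$lfc), 2.2)
  # shrunken estimates are pulled toward zero but not past it
  expect_true(all(abs(res$shrunken_lfc) <= abs(res$lfc) + 1e-9))

  # all-zero rows give NA results
  counts[1, ] <- 0
  res0 <- nb_glm_test(counts, cd, ~ cell, "cellES",
                      size_factors = rep(1, 4))
  expect_true(is.na(res0$pvalue[1]))

  expect_error(nb_glm_test(counts, cd, ~ cell, "nope"), "not in design")
  cd_bad <- tibble::tibble(cell = c("ES", "ES", "DE", "DE"),
                           extra = c(1, 1, 0, 0))  # collinear with cell
  expect_error(nb_glm_test(counts, cd_bad, ~ cell + extra, "extra"),
               "singular")
})

test_that("raw LFC estimates agree with DESeq2 on a shared dataset", {
  skip_if_not_installed("DESeq2")
  set.seed(17)
  n <- 200
  mu <- exp(runif(n, log(20), log(500)))
  fold <- rep(c(1, 2), length.out = n)
  counts <- cbind(
    matrix(rnbinom(2 * n, mu = mu * fold, size = 10), n, 2),
    matrix(rnbinom(2 * n, mu = mu, size = 10), n, 2)
  )
  colnames(counts) <- paste0("s", 1:4)
  cd <- data.frame(cell = factor(c("A", "A", "B", "B"), levels = c("B", "A")))
  res <- nb_glm_test(counts, cd, ~ cell, "cellA",
                     size_factors = rep(1, 4))

  dds <- DESeq2::DESeqDataSetFromMatrix(counts, cd, ~ cell)
  DESeq2::sizeFactors(dds) <- rep(1, 4)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  dres <- DESeq2::results(dds, name = "cell_A_vs_B")
  expect_gt(cor(res$lfc, dres$log2FoldChange, use = "complete.obs"), 0.98)
  expect_lt(median(abs(res$lfc - dres$log2FoldChange), na.rm = TRUE), 0.1)
})

test_that("observed-equals-model comparisons produce no deviation flags", {
  g <- genome_layout(c("chr1", "chr2"), c(5e5, 5e5))
  scheme <- bin_scheme_uniform(g, 1e5)
  set.seed(12)
  m <- matrix(rpois(40, 30), 4, 10,
              dimnames = list(paste0("g", 1:4), NULL))
  si <- tibble::tibble(sample_id = paste0("s", 1:4),
                       cell = c("ES", "ES", "DE", "DE"))
  obs <- lapply(1:4, function(i) mk_map(m, scheme))
  names(obs) <- si$sample_id
  out <- flag_model_deviations(obs, obs, si)
  expect_equal(nrow(out$flags), 0)
  expect_gt(out$n_tested, 0)
})

test_that("relocalization flags appear only at moved loci", {
  set.seed(5)
  g <- genome_layout("chr1", 1e7)
  scheme <- bin_scheme_uniform(g, 1e5)
  n_rna <- 40
  base <- matrix(rpois(n_rna * scheme$n_bins, 5), n_rna, scheme$n_bins,
                 dimnames = list(sprintf("g%02d", 1:n_rna), NULL))
  si <- tibble::tibble(sample_id = c("e1", "e2", "d1", "d2"),
                       cell = c("ES", "ES", "DE", "DE"))

  # uniform scaling between states: no flags
  obs <- list(e1 = mk_map(base, scheme), e2 = mk_map(base, scheme),
              d1 = mk_map(2 * base, scheme), d2 = mk_map(2 * base, scheme))
  null_out <- flag_relocalization(obs, si)
  expect_equal(nrow(null_out$flags), 0)

  # one RNA moves from bin 10 to bin 60 at constant total
  es <- base; es["g01", ] <- 0; es["g01", 10] <- 400
  de <- base; de["g01", ] <- 0; de["g01", 60] <- 400
  obs2 <- list(e1 = mk_map(es, scheme), e2 = mk_map(es, scheme),
               d1 = mk_map(de, scheme), d2 = mk_map(de, scheme))
  out2 <- flag_relocalization(obs2, si)
  moved <- out2$flags[out2$flags$rna == "g01", ]
  expect_setequal(moved$bin, c(10, 60))
  expect_equal(sum(out2$flags$rna != "g01"), 0)
})

test_that("chromatin association recovers planted enrichment factors", {
  sim <- shared_sim()
  char_info <- tibble::tibble(sample_id = sim$sample_info$sample_id,
                              cell = sim$sample_info$state)
  rna_info <- tibble::tibble(sample_id = sim$rnaseq_info$sample_id,
                             cell = sim$rnaseq_info$state)
  ca <- chromatin_association(sim$charseq_gene_counts, sim$rnaseq_counts,
                              char_info, rna_info)
  m <- dplyr::inner_join(ca, sim$truth, by = "gene_id")

  # planted 8x genes: raw score ~ 3 in every state, labeled enriched
  enr <- m[m$enrich_factor == sim$config$enrich_factor, ]
  expect_equal(median(enr$lfc_raw), 3, tolerance = 0.15)
  expect_gt(mean(enr$label == "enriched"), 0.95)
  dep <- m[m$enrich_factor == 1 / sim$config$enrich_factor, ]
  expect_gt(mean(dep$label == "depleted"), 0.95)

  # neutral genes: scores near zero, none labeled
  neu <- m[m$enrich_factor == 1, ]
  expect_lt(max(abs(median(neu$score)), abs(mean(neu$score))), 0.15)
  expect_lt(mean(neu$label != "none"), 0.01)

  # genes below the combined-count floor are excluded before fitting
  char2 <- sim$charseq_gene_counts
  rna2 <- sim$rnaseq_counts
  char2["gene0001", ] <- c(2, 1, 0, 0)
  rna2["gene0001", ] <- 0
  ca2 <- chromatin_association(char2, rna2, char_info, rna_info,
                               min_total = 10)
  expect_false("gene0001" %in% ca2$gene_id)
})
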
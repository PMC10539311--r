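uniform_kernel <- function(max_dist = 1e9) {
  structure(
    list(type = "empirical", edges = c(0, max_dist),
         density = 1 / max_dist, max_dist = max_dist, floor = 1 / max_dist,
         floor_weight = 0, n_contacts = 0, training_class = "mRNA"),
    class = "distance_kernel"
  )
}

test_that("empirical kernel integrates to 1 and recovers a power law", {
  g <- genome_layout("chr1", 3e7)
  gm <- gene_models("src", "chr1", "+", 1.5e7 - 100, 1.5e7 + 100, "mRNA",
                    genome = g)
  true_kernel <- power_law_kernel(alpha = 1.2, delta0 = 5e3,
                                  max_dist = 3e7, floor_weight = 1e-6)
  set.seed(55)
  d <- kernel_sample(true_kernel, 2e5)
  pos <- 1.5e7 + sample(c(-1, 1), 2e5, TRUE) * d
  keep <- pos >= 0 & pos < 3e7
  rec <- tibble::tibble(
    read_id = "r", rna_gene_id = "src", rna_chrom = "chr1",
    rna_pos = 1.5e7, rna_strand = "+", dna_chrom = "chr1",
    dna_pos = floor(pos[keep]), dna_strand = "+",
    annotation_class = "exon", sample_id = "s"
  )
  kern <- estimate_kernel(rec, gm, g, floor_weight = 0.01)

  # density integrates to 1 over the modeled range
  expect_equal(sum(kern$density * diff(kern$edges)), 1, tolerance = 1e-9)

  # log-log slope over the central decades within 5% of the truth
  mids <- sqrt(kern$edges[-1] * head(kern$edges, -1) + 1)
  sel <- mids > 3e4 & mids < 3e6 & kern$density > 2 * kern$floor
  slope <- coef(lm(log(kern$density[sel]) ~ log(mids[sel])))[2]
  expect_equal(unname(slope), -1.2, tolerance = 0.05)

  # too few contacts -> error
  expect_error(estimate_kernel(rec[1:10, ], gm, g), "too few")
})

test_that("kernel mass concentrates where the distances are", {
  g <- genome_layout("chr1", 1e6)
  gm <- gene_models("src", "chr1", "+", 0, 100, "mRNA", genome = g)
  rec <- tibble::tibble(
    read_id = "r", rna_gene_id = "src", rna_chrom = "chr1",
    rna_pos = 0, rna_strand = "+", dna_chrom = "chr1",
    dna_pos = rep(2000, 1500), dna_strand = "+",
    annotation_class = "exon", sample_id = "s"
  )
  kern <- estimate_kernel(rec, gm, g, min_contacts = 1000,
                          floor_weight = 0.01)
  at_mass <- kernel_density(kern, 2000)
  expect_gt(at_mass, 100 * kernel_density(kern, 5e5))
  # far from the observed distance only the uniform floor remains
  expect_equal(kernel_density(kern, 5e5), kern$floor)
})

test_that("bias estimation uses trans coverage with a pseudocount", {
  g <- genome_layout(c("chr1", "chr2"), c(3e5, 1e5))
  scheme <- bin_scheme_uniform(g, 1e5)  # 3 + 1 bins
  gm <- gene_models(c("m2", "m1"), c("chr2", "chr1"), c("+", "+"),
                    c(0, 0), c(1000, 1000), c("mRNA", "mRNA"), genome = g)
  counts <- Matrix::sparseMatrix(
    i = c(1, 1, 2), j = c(1, 3, 4), x = c(4, 4, 6), dims = c(2, 4),
    dimnames = list(c("m2", "m1"), NULL)
  )
  cm <- contact_matrix(counts, scheme)
  bias <- estimate_bias(cm, gm, pseudocount = 0.5)
  # chr1 bins see coverage [4, 0, 4] from the chr2 mRNA; chr2's bin sees
  # 6 from the chr1 mRNA; each gets +0.5 and the whole vector sums to 1
  expect_equal(bias$values, c(4.5, 0.5, 4.5, 6.5) / 16)
  expect_equal(sum(bias$values), 1)
  # a cis-only matrix has no trans coverage
  cis_only <- contact_matrix(Matrix::sparseMatrix(
    i = 2, j = 1, x = 5, dims = c(2, 4),
    dimnames = list(c("m2", "m1"), NULL)), scheme)
  expect_error(estimate_bias(cis_only, gm), "no trans")
})

test_that("cis probabilities equal the direct bias-times-kernel product", {
  kern <- uniform_kernel()
  # uniform kernel and bias over 2 bins -> 1/2 each
  expect_equal(cis_probabilities(100, kern, c(1, 1), c(50, 150)),
               c(0.5, 0.5))
  expect_error(cis_probabilities(numeric(0), kern, c(1, 1), c(50, 150)),
               "no source")

  # two-valued step kernel, one source position: direct evaluation
  step_kern <- structure(
    list(type = "empirical", edges = c(0, 100, 1e4),
         density = c(8e-4, 2e-5), max_dist = 1e4, floor = 1e-9,
         floor_weight = 0, n_contacts = 0, training_class = "mRNA"),
    class = "distance_kernel"
  )
  bias <- c(2, 1, 5, 2)
  mids <- c(50, 150, 250, 350)
  p <- cis_probabilities(300, step_kern, bias, mids)
  rho <- c(2e-5, 2e-5, 8e-4, 8e-4)  # |mid - 300| vs the 100 bp edge
  expect_equal(p, bias * rho / sum(bias * rho))
  expect_equal(sum(p), 1)
})

test_that("expected maps preserve per-chromosome totals and uniformity", {
  sim <- shared_sim()
  maps <- shared_maps()
  kern <- shared_kernel()
  bias <- shared_bias()
  pred <- predict_expected_map(maps[[1]], kern, bias, sim$gene_models)
  expect_equal(chrom_totals(pred), chrom_totals(maps[[1]]),
               tolerance = 1e-12)

  # uniform bias: trans expectations are flat within a chromosome
  g <- genome_layout(c("chr1", "chr2"), c(4e5, 4e5))
  scheme <- bin_scheme_uniform(g, 1e5)
  gm <- gene_models("r1", "chr1", "+", 0, 1000, "lncRNA", genome = g)
  counts <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 5), x = c(10, 40),
                                 dims = c(1, 8),
                                 dimnames = list("r1", NULL))
  cm <- contact_matrix(counts, scheme)
  ubias <- structure(list(values = rep(1 / 8, 8), scheme = scheme,
                          pseudocount = 0, training_class = "mRNA"),
                     class = "dna_bias")
  pred2 <- predict_expected_map(cm, uniform_kernel(), ubias, gm)
  expect_equal(as.numeric(pred2$counts[1, 5:8]), rep(10, 4))

  # toy 1-RNA hand computation: bias (1,3) on cis bins, uniform kernel
  bias3 <- structure(list(values = c(1, 3, 4) / 8, scheme = NULL,
                          pseudocount = 0, training_class = "mRNA"),
                     class = "dna_bias")
  g3 <- genome_layout("c", 2e5)
  s3 <- bin_scheme_uniform(g3, 1e5)
  bias3$scheme <- s3
  gm3 <- gene_models("r1", "c", "+", 0, 100, "lncRNA", genome = g3)
  cm3 <- contact_matrix(Matrix::sparseMatrix(i = 1, j = 1, x = 8,
                                             dims = c(1, 2),
                                             dimnames = list("r1", NULL)),
                        s3)
  bias3$values <- c(1, 3) / 4
  p3 <- predict_expected_map(cm3, uniform_kernel(), bias3, gm3)
  expect_equal(as.numeric(p3$counts[1, ]), 8 * c(1, 3) / 4)
})

test_that("model realizations conserve totals exactly and are seeded", {
  sim <- shared_sim()
  maps <- shared_maps()
  kern <- shared_kernel()
  bias <- shared_bias()
  m1 <- simulate_model_map(maps[[1]], kern, bias, sim$gene_models, seed = 5)
  m2 <- simulate_model_map(maps[[1]], kern, bias, sim$gene_models, seed = 5)
  expect_identical(as.matrix(m1$counts), as.matrix(m2$counts))
  expect_equal(chrom_totals(m1), chrom_totals(maps[[1]]))
  expect_true(all(m1$counts >= 0))
})

test_that("multinomial frequencies match probabilities at large counts", {
  g <- genome_layout(c("chr1", "chr2"), c(1e6, 1e6))
  scheme <- bin_scheme_uniform(g, 1e5)
  gm <- gene_models("r1", "chr1", "+", 4e5, 4.1e5, "lncRNA", genome = g)
  counts <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 11), x = c(1e6, 1e6),
                                 dims = c(1, 20),
                                 dimnames = list("r1", NULL))
  cm <- contact_matrix(counts, scheme)
  set.seed(2)
  v <- runif(20) + 0.2
  bias <- structure(list(values = v / sum(v), scheme = scheme,
                         pseudocount = 0, training_class = "mRNA"),
                    class = "dna_bias")
  kern <- power_law_kernel(1.2, 5e3, max_dist = 1e6, floor_weight = 0.1)
  mm <- simulate_model_map(cm, kern, bias, gm, seed = 8)
  pred <- predict_expected_map(cm, kern, bias, gm)
  expected <- as.numeric(pred$counts[1, ])
  x <- as.numeric(mm$counts[1, ])
  n_chr <- 1e6  # conditioning total per chromosome
  z <- abs(x - expected) / sqrt(expected * (1 - expected / n_chr))
  # per-bin normal approximation: nearly all bins within 3 sigma, all
  # within 5
  expect_gt(mean(z <= 3), 0.95)
  expect_true(all(z <= 5))
})
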
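# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The reference synthetic dataset: default study conditions, seed 42.
shared_sim <- function() {
  fixture("sim", function() simulate_dataset(sim_config(), seed = 42))
}

# Per-sample 100 kb contact matrices of the shared dataset.
shared_maps <- function() {
  fixture("maps", function() {
    sim <- shared_sim()
    scheme <- bin_scheme_uniform(sim$genome, 1e5)
    idx <- split(seq_len(nrow(sim$records)), sim$records$sample_id)
    maps <- lapply(idx, function(ix) {
      bin_contacts(sim$records[ix, ], scheme,
                   rna_ids = sim$gene_models$gene_id,
                   sample_id = sim$records$sample_id[ix[1]])
    })
    maps[sim$sample_info$sample_id]
  })
}

shared_kernel <- function() {
  fixture("kernel", function() {
    sim <- shared_sim()
    estimate_kernel(sim$records, sim$gene_models, sim$genome)
  })
}

shared_bias <- function() {
  fixture("bias", function() {
    sim <- shared_sim()
    estimate_bias(shared_maps()[[1]], sim$gene_models)
  })
}

# Minimal two-chromosome genome for hand-built cases.
tiny_genome <- function() genome_layout(c("chr1", "chr2"), c(1e6, 2e6))

# Hand-built contact records with valid coordinates on tiny_genome().
make_records <- function(n, genome = tiny_genome(), seed = 1,
                         genes = c("gA", "gB", "gC")) {
  set.seed(seed)
  chroms <- genome_names(genome)
  rc <- sample(chroms, n, replace = TRUE)
  dc <- sample(chroms, n, replace = TRUE)
  tibble::tibble(
    read_id = sprintf("r%05d", seq_len(n)),
    rna_gene_id = sample(genes, n, replace = TRUE),
    rna_chrom = rc,
    rna_pos = floor(runif(n, 0, chrom_length(genome, rc))),
    rna_strand = sample(c("+", "-"), n, replace = TRUE),
    dna_chrom = dc,
    dna_pos = floor(runif(n, 0, chrom_length(genome, dc))),
    dna_strand = sample(c("+", "-"), n, replace = TRUE),
    annotation_class = sample(c("exon", "intron", "intergenic"), n,
                              replace = TRUE),
    sample_id = "s1"
  )
}

# A betabin_glm_fit with known parameters (for simulators and oracles).
make_fit <- function(eta_chr = stats::qlogis(c(chr1 = 0.3, chr2 = 0.4)),
                     eta_expr = 0, gamma = 0.02) {
  structure(
    list(eta_chr = eta_chr, eta_expr = eta_expr, gamma = gamma,
         mode = "trans", converged = TRUE),
    class = "betabin_glm_fit"
  )
}
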
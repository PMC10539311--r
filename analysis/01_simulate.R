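#!/usr/bin/env Rscript
# Step 1: generate the synthetic ChAR-seq-style study dataset.
#
# Two cell states (ES, DE) x two replicates, 500 RNAs on a 3 x 30 Mb
# genome, 2e5 contacts per sample, with planted trans/cis-delocalized,
# ultralocalized, XIST-like and peak-bearing RNAs, plus paired total
# RNA-seq counts with planted chromatin-enrichment factors. Everything
# downstream reads from results/data/.

suppressPackageStartupMessages(library(chartographer))

seed <- 42
outdir <- "results/data"

cfg <- sim_config()
sim <- simulate_dataset(cfg, seed = seed)
write_dataset(sim, outdir)
saveRDS(sim, file.path(outdir, "sim.rds"))  # scratch convenience for 02-05

cat("Samples:", paste(sim$sample_info$sample_id, collapse = ", "), "\n")
cat("Contacts per sample:", cfg$depth, "\n")
cat("Planted effects:\n")
print(table(sim$truth$planted))
cat("Pairs files, GTF, chrom.sizes, RNA-seq counts and the truth table",
    "are in", outdir, "\n")
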
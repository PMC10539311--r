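#' Empirical distance-decay kernel
#'
#' Estimates the per-bp contact density as a function of absolute
#' RNA-to-DNA travel distance, from the cis contacts of a training class
#' (protein-coding RNAs by default). The histogram uses log-spaced bins
#' (25 per decade from `min_dist` to the longest chromosome), converted
#' to per-bp density, then mixed with a uniform floor (weight
#' `floor_weight`) so that unobserved distances keep non-zero density.
#' The density integrates to 1 over the modeled range.
#'
#' @param records Contact-record tibble.
#' @param gene_models Gene-model tibble identifying the training class.
#' @param genome A [genome_layout()].
#' @param training_class RNA class used for estimation.
#' @param bins_per_decade Log-histogram resolution.
#' @param min_dist Lower edge of the first log bin (bp); a linear bin
#'   [0, min_dist) catches shorter distances.
#' @param floor_weight Mixing weight of the uniform background floor.
#' @param min_contacts Minimum cis training contacts required.
#' @return An object of class `distance_kernel`.
#' @export
estimate_kernel <- function(records, gene_models, genome,
                            training_class = "mRNA", bins_per_decade = 25,
                            min_dist = 100, floor_weight = 0.01,
                            min_contacts = 1000) {
  gi <- match(records$rna_gene_id, gene_models$gene_id)
  keep <- !is.na(gi) & gene_models$rna_class[gi] == training_class &
    records$rna_chrom == records$dna_chrom
  d <- abs(records$dna_pos[keep] - records$rna_pos[keep])
  if (length(d) < min_contacts) {
    stop("too few cis training contacts for kernel estimation (",
         length(d), " < ", min_contacts, ")")
  }
  max_dist <- max(genome$chrom)
  edges <- c(0, 10^seq(log10(min_dist), log10(max_dist),
                       by = 1 / bins_per_decade))
  edges[length(edges)] <- max_dist
  counts <- tabulate(findInterval(pmin(d, max_dist - 1), edges),
                     nbins = length(edges) - 1)
  widths <- diff(edges)
  dens <- counts / widths / sum(counts)
  dens <- (1 - floor_weight) * dens + floor_weight / max_dist
  structure(
    list(type = "empirical", edges = edges, density = dens,
         max_dist = max_dist, floor = floor_weight / max_dist,
         floor_weight = floor_weight, n_contacts = length(d),
         training_class = training_class),
    class = "distance_kernel"
  )
}

#' Parametric truncated power-law kernel
#'
#' A smooth distance-decay kernel used by the synthetic-data generator:
#' density(d) proportional to (d + delta0)^(-alpha) on [0, max_dist),
#' mixed with a uniform floor of weight `floor_weight`. Normalized to
#' integrate to 1.
#'
#' @param alpha Power-law exponent (> 0, != 1).
#' @param delta0 Offset (bp) regularizing the density at d = 0.
#' @param max_dist Upper truncation (bp).
#' @param floor_weight Mixing weight of the uniform component.
#' @return An object of class `distance_kernel`.
#' @export
power_law_kernel <- function(alpha = 1.2, delta0 = 5000, max_dist = 3e7,
                             floor_weight = 0.05) {
  stopifnot(alpha > 0, abs(alpha - 1) > 1e-9, delta0 > 0, max_dist > delta0)
  # integral of (d + delta0)^-alpha over [0, max_dist)
  Z <- ((max_dist + delta0)^(1 - alpha) - delta0^(1 - alpha)) / (1 - alpha)
  structure(
    list(type = "power_law", alpha = alpha, delta0 = delta0,
         max_dist = max_dist, floor_weight = floor_weight, Z = Z,
         floor = floor_weight / max_dist),
    class = "distance_kernel"
  )
}

#' @export
print.distance_kernel <- function(x, ...) {
  if (x$type == "empirical") {
    cat("<distance_kernel> empirical, ", length(x$density), " log bins, ",
        format(x$n_contacts, big.mark = ","), " contacts\n", sep = "")
  } else {
    cat(sprintf("<distance_kernel> power law, alpha=%.3g delta0=%.3g\n",
                x$alpha, x$delta0))
  }
  invisible(x)
}

#' Evaluate a distance kernel's per-bp density
#'
#' @param kernel A `distance_kernel`.
#' @param dist Distances in bp (sign is ignored; the kernel is
#'   symmetric).
#' @return Per-bp density values; distances beyond the modeled range get
#'   the uniform floor.
#' @export
kernel_density <- function(kernel, dist) {
  d <- abs(dist)
  if (kernel$type == "empirical") {
    idx <- findInterval(d, kernel$edges)
    out <- rep(kernel$floor, length(d))
    ok <- idx >= 1 & idx <= length(kernel$density)
    out[ok] <- kernel$density[idx[ok]]
    out
  } else {
    w <- kernel$floor_weight
    out <- (1 - w) * (d + kernel$delta0)^(-kernel$alpha) / kernel$Z +
      w / kernel$max_dist
    out[d >= kernel$max_dist] <- kernel$floor
    out
  }
}

#' Sample absolute distances from a parametric kernel
#'
#' Direct inverse-CDF sampler for [power_law_kernel()] (with the uniform
#' component sampled by mixture), independent of the bin-level placement
#' used elsewhere.
#'
#' @param kernel A parametric `distance_kernel`.
#' @param n Number of draws.
#' @return Numeric vector of distances in [0, max_dist).
#' @export
kernel_sample <- function(kernel, n) {
  stopifnot(kernel$type == "power_law")
  u <- runif(n)
  from_floor <- runif(n) < kernel$floor_weight
  a <- kernel$alpha
  d0 <- kernel$delta0
  x <- (d0^(1 - a) + u * ((kernel$max_dist + d0)^(1 - a) - d0^(1 - a)))^
    (1 / (1 - a)) - d0
  x[from_floor] <- runif(sum(from_floor), 0, kernel$max_dist)
  x
}

#' DNA-locus bias from trans-chromosomal mRNA coverage
#'
#' For each genomic bin, sums the contacts from training-class RNAs whose
#' source chromosome differs from the bin's chromosome, adds a
#' pseudocount per bin (so every bin keeps positive probability), and
#' normalizes to sum to 1 genome-wide.
#'
#' @param cm A `contact_matrix`.
#' @param gene_models Gene-model tibble.
#' @param training_class RNA class providing the coverage.
#' @param pseudocount Added to every bin before normalization.
#' @return An object of class `dna_bias` with fields `values` (length =
#'   number of bins, sums to 1), `scheme`, `pseudocount`.
#' @export
estimate_bias <- function(cm, gene_models, training_class = "mRNA",
                          pseudocount = 0.5) {
  bins <- scheme_bins(cm$scheme)
  gi <- match(rownames(cm$counts), gene_models$gene_id)
  is_tr <- !is.na(gi) & gene_models$rna_class[gi] == training_class
  src <- gene_models$chrom[gi]
  if (!any(is_tr)) stop("no training-class RNAs in the contact matrix")
  v <- numeric(nrow(bins))
  total_trans <- 0
  for (ch in unique(bins$chrom)) {
    rows <- which(is_tr & src != ch)
    cols <- which(bins$chrom == ch)
    if (length(rows) > 0) {
      v[cols] <- as.numeric(colSums(cm$counts[rows, cols, drop = FALSE]))
      total_trans <- total_trans + sum(v[cols])
    }
  }
  if (total_trans == 0) stop("no trans-chromosomal training contacts")
  v <- v + pseudocount
  structure(
    list(values = v / sum(v), scheme = cm$scheme, pseudocount = pseudocount,
         training_class = training_class),
    class = "dna_bias"
  )
}

#' Cis contact probabilities for one RNA
#'
#' Probability that a cis contact of an RNA with source positions
#' `source_positions` lands in each bin of its source chromosome:
#' proportional to the bin's DNA bias times the summed kernel density
#' from each source position to the bin midpoint, normalized over the
#' chromosome's bins.
#'
#' @param source_positions Numeric vector of RNA-side source coordinates
#'   (bp) on the chromosome.
#' @param kernel A `distance_kernel`.
#' @param bias_values Per-bin bias for the chromosome's bins.
#' @param bin_mids Bin midpoints (bp), same length as `bias_values`.
#' @return Probability vector summing to 1.
#' @export
cis_probabilities <- function(source_positions, kernel, bias_values,
                              bin_mids) {
  if (length(source_positions) == 0) stop("no source positions supplied")
  stopifnot(length(bias_values) == length(bin_mids))
  rho <- outer(bin_mids, source_positions, function(d, r) {
    kernel_density(kernel, d - r)
  })
  p <- bias_values * rowSums(rho)
  p / sum(p)
}

# Shared helper: per-RNA per-chromosome probability vectors of the
# generative model. Returns a list keyed by chromosome of functions or
# vectors; cis vectors depend on the RNA.
model_probabilities <- function(cm, kernel, bias, gene_models,
                                source_positions = NULL) {
  bins <- scheme_bins(cm$scheme)
  chroms <- genome_names(cm$scheme$genome)
  rna <- rownames(cm$counts)
  gi <- match(rna, gene_models$gene_id)
  if (anyNA(gi)) stop("contact matrix rows absent from gene models")
  trans_p <- lapply(setNames(chroms, chroms), function(ch) {
    v <- bias$values[bins$chrom == ch]
    v / sum(v)
  })
  bin_idx <- lapply(setNames(chroms, chroms),
                    function(ch) which(bins$chrom == ch))
  src_of <- function(i) {
    g <- rna[i]
    if (!is.null(source_positions) && !is.null(source_positions[[g]])) {
      source_positions[[g]]
    } else {
      (gene_models$start[gi[i]] + gene_models$end[gi[i]]) / 2
    }
  }
  list(bins = bins, chroms = chroms, rna = rna, gi = gi,
       trans_p = trans_p, bin_idx = bin_idx, src_of = src_of)
}

#' Expected contact map under the generative model
#'
#' For each RNA and each chromosome, distributes the observed
#' per-chromosome total over the chromosome's bins: on the source
#' chromosome with [cis_probabilities()] (bias x kernel around the RNA's
#' source positions), on trans chromosomes proportional to the DNA bias
#' renormalized within the chromosome. Per-RNA per-chromosome expected
#' totals equal the observed totals exactly (the model is conditioned on
#' them).
#'
#' @param cm The conditioning `contact_matrix`.
#' @param kernel A `distance_kernel`.
#' @param bias A `dna_bias` on the same bin scheme.
#' @param gene_models Gene-model tibble (source chromosome and default
#'   source position = gene midpoint).
#' @param source_positions Optional named list (by gene id) of source
#'   position vectors overriding the gene-midpoint default.
#' @return A `contact_matrix` whose counts are expected (real-valued)
#'   contacts.
#' @export
predict_expected_map <- function(cm, kernel, bias, gene_models,
                                 source_positions = NULL) {
  if (!identical(bias$scheme$n_bins, cm$scheme$n_bins)) {
    stop("bias and contact matrix use different bin schemes")
  }
  mp <- model_probabilities(cm, kernel, bias, gene_models, source_positions)
  ct <- chrom_totals(cm)
  out <- matrix(0, nrow(cm$counts), ncol(cm$counts),
                dimnames = dimnames(cm$counts))
  for (i in seq_along(mp$rna)) {
    src_chrom <- gene_models$chrom[mp$gi[i]]
    for (ch in mp$chroms) {
      tot <- ct[i, ch]
      if (tot == 0) next
      idx <- mp$bin_idx[[ch]]
      p <- if (ch == src_chrom) {
        cis_probabilities(mp$src_of(i), kernel, bias$values[idx],
                          mp$bins$mid[idx])
      } else {
        mp$trans_p[[ch]]
      }
      out[i, idx] <- tot * p
    }
  }
  contact_matrix(Matrix(out, sparse = TRUE), cm$scheme,
                 sample_id = paste0(cm$sample_id %||% "map", "_expected"))
}

#' Simulate one realization of the generative model
#'
#' Draws, for each RNA and each chromosome, a multinomial sample of the
#' observed per-chromosome total over the model's bin probabilities.
#' Per-RNA per-chromosome totals in the simulated map equal the observed
#' totals exactly; the draw is deterministic given `seed`.
#'
#' @inheritParams predict_expected_map
#' @param seed Integer seed.
#' @return A `contact_matrix` of simulated integer counts.
#' @export
simulate_model_map <- function(cm, kernel, bias, gene_models, seed,
                               source_positions = NULL) {
  set.seed(seed)
  mp <- model_probabilities(cm, kernel, bias, gene_models, source_positions)
  ct <- chrom_totals(cm)
  triplets_i <- integer(0)
  triplets_j <- integer(0)
  triplets_x <- numeric(0)
  for (i in seq_along(mp$rna)) {
    src_chrom <- gene_models$chrom[mp$gi[i]]
    for (ch in mp$chroms) {
      tot <- ct[i, ch]
      if (tot == 0) next
      idx <- mp$bin_idx[[ch]]
      p <- if (ch == src_chrom) {
        cis_probabilities(mp$src_of(i), kernel, bias$values[idx],
                          mp$bins$mid[idx])
      } else {
        mp$trans_p[[ch]]
      }
      x <- drop(rmultinom(1, tot, p))
      nz <- which(x > 0)
      triplets_i <- c(triplets_i, rep.int(i, length(nz)))
      triplets_j <- c(triplets_j, idx[nz])
      triplets_x <- c(triplets_x, x[nz])
    }
  }
  counts <- sparseMatrix(i = triplets_i, j = triplets_j, x = triplets_x,
                         dims = dim(cm$counts),
                         dimnames = dimnames(cm$counts))
  contact_matrix(counts, cm$scheme,
                 sample_id = paste0(cm$sample_id %||% "map", "_model"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
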
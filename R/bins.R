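#' Uniform genomic bin scheme
#'
#' Tiles each chromosome of a genome with disjoint fixed-width bins that
#' cover it completely (the last bin of each chromosome may be short).
#' Bins are indexed 1..n genome-wide in chromosome order.
#'
#' @param genome A [genome_layout()].
#' @param bin_size Bin width in bp.
#' @return An object of class `bin_scheme`.
#' @export
bin_scheme_uniform <- function(genome, bin_size) {
  stopifnot(bin_size > 0)
  n_per <- ceiling(genome$chrom / bin_size)
  offset <- c(0, cumsum(n_per))[seq_along(n_per)]
  names(offset) <- genome_names(genome)
  structure(
    list(type = "uniform", bin_size = bin_size, genome = genome,
         n_per_chrom = n_per, offset = offset, n_bins = sum(n_per)),
    class = "bin_scheme"
  )
}

#' Explicit-window bin scheme
#'
#' A scheme made of named windows. Windows may overlap; overlap is
#' detected and recorded in the `overlapping` field, and point lookups
#' then return every containing window.
#'
#' @param windows Tibble with columns `chrom`, `start`, `end` and
#'   optionally `label`.
#' @param genome A [genome_layout()].
#' @return An object of class `bin_scheme`.
#' @export
bin_scheme_windows <- function(windows, genome) {
  stopifnot(all(c("chrom", "start", "end") %in% colnames(windows)))
  if (!"label" %in% colnames(windows)) {
    windows$label <- sprintf("win%05d", seq_len(nrow(windows)))
  }
  gr <- GRanges(windows$chrom, IRanges(windows$start + 1, windows$end))
  ov <- findOverlaps(gr, gr)
  overlapping <- any(queryHits(ov) != subjectHits(ov))
  structure(
    list(type = "windows", windows = windows, genome = genome,
         granges = gr, n_bins = nrow(windows), overlapping = overlapping),
    class = "bin_scheme"
  )
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat("<bin_scheme> ", x$type, ", ", x$n_bins, " bins\n", sep = "")
  invisible(x)
}

scheme_n_bins <- function(scheme) scheme$n_bins

#' Bin coordinate table of a scheme
#'
#' @param scheme A `bin_scheme`.
#' @return Tibble with columns `bin`, `chrom`, `start`, `end`, `mid`.
#' @export
scheme_bins <- function(scheme) {
  if (scheme$type == "uniform") {
    g <- scheme$genome
    chroms <- rep(genome_names(g), scheme$n_per_chrom)
    idx <- unlist(lapply(scheme$n_per_chrom, seq_len), use.names = FALSE) - 1
    start <- idx * scheme$bin_size
    end <- pmin(start + scheme$bin_size, chrom_length(g, chroms))
    tibble(bin = seq_len(scheme$n_bins), chrom = chroms, start = start,
           end = end, mid = (start + end) / 2)
  } else {
    w <- scheme$windows
    tibble(bin = seq_len(nrow(w)), chrom = w$chrom, start = w$start,
           end = w$end, mid = (w$start + w$end) / 2, label = w$label)
  }
}

# Vectorized point -> global bin index for uniform schemes; NA when the
# chromosome is not part of the scheme.
assign_bin_uniform <- function(scheme, chrom, pos) {
  off <- scheme$offset[chrom]
  unname(off + floor(pos / scheme$bin_size) + 1)
}

#' Bin contacts into a sparse RNA x bin count matrix
#'
#' Each record is assigned to the bin containing its DNA-side position
#' (point assignment). Records on chromosomes absent from the scheme are
#' counted as unassigned with a warning, not an error, so scaffold
#' contigs can be tolerated.
#'
#' @param records Contact-record tibble.
#' @param scheme A uniform [bin_scheme_uniform()].
#' @param rna_ids Optional character vector fixing the row universe and
#'   order; defaults to the sorted RNAs present in `records`.
#' @param sample_id Optional sample tag stored on the matrix.
#' @return An object of class `contact_matrix`: a sparse count matrix
#'   with RNAs as rows and bins as columns, plus the scheme and caches of
#'   per-RNA and per-RNA-per-chromosome totals.
#' @export
bin_contacts <- function(records, scheme, rna_ids = NULL, sample_id = NULL) {
  stopifnot(inherits(scheme, "bin_scheme"), scheme$type == "uniform")
  if (is.null(rna_ids)) rna_ids <- sort(unique(records$rna_gene_id))
  known <- records$dna_chrom %in% genome_names(scheme$genome)
  n_unassigned <- sum(!known)
  if (n_unassigned > 0) {
    warning(n_unassigned, " record(s) on chromosomes outside the bin ",
            "scheme were left unassigned")
  }
  rec <- records[known, , drop = FALSE]
  i <- match(rec$rna_gene_id, rna_ids)
  if (anyNA(i)) stop("records contain RNAs absent from rna_ids")
  j <- assign_bin_uniform(scheme, rec$dna_chrom, rec$dna_pos)
  counts <- sparseMatrix(
    i = i, j = j, x = rep(1, nrow(rec)),
    dims = c(length(rna_ids), scheme$n_bins),
    dimnames = list(rna_ids, NULL)
  )
  contact_matrix(counts, scheme, sample_id = sample_id,
                 unassigned = n_unassigned)
}

#' Construct a contact matrix object
#'
#' @param counts RNA x bin matrix (sparse or dense), non-negative.
#' @param scheme The [bin_scheme_uniform()] indexing the columns.
#' @param sample_id Optional sample tag.
#' @param unassigned Number of input records that could not be binned.
#' @return A `contact_matrix`.
#' @export
contact_matrix <- function(counts, scheme, sample_id = NULL, unassigned = 0) {
  stopifnot(ncol(counts) == scheme$n_bins)
  if (min(counts) < 0) stop("contact counts must be non-negative")
  structure(
    list(counts = counts, scheme = scheme, sample_id = sample_id,
         unassigned = unassigned),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", nrow(x$counts), " RNAs x ", ncol(x$counts),
      " bins, ", format(sum(x$counts), big.mark = ","), " contacts",
      if (!is.null(x$sample_id)) paste0(" [", x$sample_id, "]"), "\n",
      sep = "")
  invisible(x)
}

#' Per-RNA total contact counts (N_i)
#' @param cm A `contact_matrix`.
#' @return Named numeric vector of row sums.
#' @export
contact_totals <- function(cm) {
  setNames(as.numeric(rowSums(cm$counts)), rownames(cm$counts))
}

#' Per-RNA per-chromosome contact totals
#'
#' @param cm A `contact_matrix`.
#' @return Numeric matrix RNAs x chromosomes; row sums equal
#'   [contact_totals()].
#' @export
chrom_totals <- function(cm) {
  bins <- scheme_bins(cm$scheme)
  chroms <- genome_names(cm$scheme$genome)
  ind <- sparseMatrix(
    i = seq_len(nrow(bins)), j = match(bins$chrom, chroms),
    x = 1, dims = c(nrow(bins), length(chroms))
  )
  out <- as.matrix(cm$counts %*% ind)
  dimnames(out) <- list(rownames(cm$counts), chroms)
  out
}
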
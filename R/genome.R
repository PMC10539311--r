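#' Genome layout
#'
#' A minimal description of the genome over which contacts are recorded:
#' an ordered set of chromosome names and their lengths in bp. All
#' coordinates in the package are 0-based half-open; on-disk pairs files
#' use 1-based positions (see [read_pairs()]).
#'
#' @param chrom_names Character vector of unique chromosome identifiers.
#' @param chrom_lengths Numeric vector of chromosome lengths (bp), all > 0.
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths)) {
    stop("chrom_names and chrom_lengths must have the same length")
  }
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("all chromosome lengths must be finite and > 0")
  }
  structure(
    list(chrom = setNames(chrom_lengths, chrom_names)),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom), " chromosomes, ",
      format(sum(x$chrom), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

genome_names <- function(genome) names(genome$chrom)
genome_length <- function(genome) sum(genome$chrom)
chrom_length <- function(genome, chrom) unname(genome$chrom[chrom])

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a tab-separated file with columns chromosome name
#'   and length in bp.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  genome_layout(x$chrom, x$length)
}

#' Write a chrom.sizes file
#' @param genome A [genome_layout()].
#' @param path Output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  writeLines(paste(genome_names(genome), genome$chrom, sep = "\t"), path)
  invisible(path)
}

#' Gene model table
#'
#' Builds and validates a tibble of gene models. Coordinates are 0-based
#' half-open. The strand-aware 5' end (`tss`) and 3' end (`end3`) are
#' derived columns: for "+" genes tss = start and end3 = end; for "-"
#' genes tss = end and end3 = start.
#'
#' @param gene_id,chrom,strand,start,end,rna_class Per-gene vectors;
#'   `strand` in `+`/`-`; `rna_class` a free-form label such as "mRNA",
#'   "lncRNA", "ncRNA:snRNA" or "UTL".
#' @param genome Optional [genome_layout()] used to bound-check intervals.
#' @return A tibble with the input columns plus `tss` and `end3`.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end, rna_class,
                        genome = NULL) {
  gm <- tibble(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    start = as.numeric(start),
    end = as.numeric(end),
    rna_class = as.character(rna_class)
  )
  if (anyDuplicated(gm$gene_id)) stop("gene ids must be unique")
  if (!all(gm$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(gm$start < 0) || any(gm$start >= gm$end)) {
    stop("gene intervals must satisfy 0 <= start < end")
  }
  if (!is.null(genome)) {
    len <- chrom_length(genome, gm$chrom)
    if (anyNA(len)) {
      stop("gene chromosome not in genome: ",
           paste(unique(gm$chrom[is.na(len)]), collapse = ", "))
    }
    if (any(gm$end > len)) stop("gene interval exceeds chromosome length")
  }
  gm$tss <- ifelse(gm$strand == "+", gm$start, gm$end)
  gm$end3 <- ifelse(gm$strand == "+", gm$end, gm$start)
  gm
}

#' Read gene models from a GTF file
#'
#' Imports `gene`-type records from a GTF file (1-based inclusive on disk)
#' and converts them to the internal 0-based half-open convention. The
#' `gene_type` attribute, when present, is used as the RNA class.
#'
#' @param path Path to a GTF file.
#' @param genome Optional [genome_layout()] for bound checks.
#' @return A gene-model tibble as from [gene_models()].
#' @export
read_gene_models_gtf <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  if ("type" %in% colnames(md)) {
    keep <- md$type == "gene"
    if (any(keep)) md <- md[keep, , drop = FALSE]
  }
  cls <- if ("gene_type" %in% colnames(md)) md$gene_type else "gene"
  gene_models(
    gene_id = md$gene_id,
    chrom = as.character(md$seqnames),
    strand = as.character(md$strand),
    start = md$start - 1L,
    end = md$end,
    rna_class = cls,
    genome = genome
  )
}

#' Write gene models to a GTF file
#'
#' @param gm A gene-model tibble.
#' @param path Output path.
#' @param source Value for the GTF source field.
#' @export
write_gene_models_gtf <- function(gm, path, source = "chartographer") {
  gr <- GRanges(
    seqnames = gm$chrom,
    ranges = IRanges(start = gm$start + 1L, end = gm$end),
    strand = gm$strand
  )
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$gene_id <- gm$gene_id
  S4Vectors::mcols(gr)$gene_type <- gm$rna_class
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
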
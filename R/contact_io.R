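PAIRS_COLUMNS <- c("readID", "chrom1", "pos1", "strand1", "chrom2", "pos2",
                   "strand2", "gene_id", "annot", "sample")

ANNOTATION_CLASSES <- c("exon", "intron", "intergenic")

#' Read RNA-DNA contact records from a pairs-style file
#'
#' The on-disk dialect is a tab-separated text file with `#`-prefixed
#' header lines, one of which must be
#' `#columns: readID chrom1 pos1 strand1 chrom2 pos2 strand2 gene_id annot sample`
#' with the RNA side first (chrom1/pos1/strand1). Positions on disk are
#' 1-based (pairs-format convention) and converted to the internal
#' 0-based half-open convention.
#'
#' @param path Path to a pairs file.
#' @param genome A [genome_layout()]; records on chromosomes absent from
#'   it, or with out-of-bounds positions, raise an error naming the line.
#' @return A tibble of contact records with columns `read_id`,
#'   `rna_gene_id`, `rna_chrom`, `rna_pos`, `rna_strand`, `dna_chrom`,
#'   `dna_pos`, `dna_strand`, `annotation_class`, `sample_id`.
#' @export
read_pairs <- function(path, genome) {
  if (!file.exists(path)) stop("pairs file not found: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  header <- lines[is_comment]
  if (!any(startsWith(header, "#columns:"))) {
    stop("pairs header must declare a '#columns:' line")
  }
  decl <- sub("^#columns:\\s*", "", grep("^#columns:", header, value = TRUE)[1])
  decl_cols <- strsplit(trimws(decl), "\\s+")[[1]]
  if (!identical(decl_cols, PAIRS_COLUMNS)) {
    stop("unsupported pairs column order: ", decl)
  }
  data_idx <- which(!is_comment & nzchar(lines))
  if (length(data_idx) == 0L) return(empty_contact_records())
  parts <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 10L)) {
    bad <- which(nf != 10L)[1]
    stop(sprintf("malformed pairs line %d: expected 10 fields, got %d",
                 data_idx[bad], nf[bad]))
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 10L, byrow = TRUE)
  pos1 <- suppressWarnings(as.numeric(m[, 3]))
  pos2 <- suppressWarnings(as.numeric(m[, 6]))
  if (anyNA(pos1) || anyNA(pos2)) {
    bad <- which(is.na(pos1) | is.na(pos2))[1]
    stop(sprintf("malformed pairs line %d: non-numeric position",
                 data_idx[bad]))
  }
  check_chrom_bounds(m[, 2], pos1, genome, data_idx, "RNA")
  check_chrom_bounds(m[, 5], pos2, genome, data_idx, "DNA")
  bad_annot <- !(m[, 9] %in% ANNOTATION_CLASSES)
  if (any(bad_annot)) {
    stop(sprintf("malformed pairs line %d: unknown annotation class '%s'",
                 data_idx[which(bad_annot)[1]], m[which(bad_annot)[1], 9]))
  }
  tibble(
    read_id = m[, 1],
    rna_gene_id = m[, 8],
    rna_chrom = m[, 2],
    rna_pos = pos1 - 1,
    rna_strand = m[, 4],
    dna_chrom = m[, 5],
    dna_pos = pos2 - 1,
    dna_strand = m[, 7],
    annotation_class = m[, 9],
    sample_id = m[, 10]
  )
}

check_chrom_bounds <- function(chrom, pos1based, genome, line_no, side) {
  len <- chrom_length(genome, chrom)
  if (anyNA(len)) {
    bad <- which(is.na(len))[1]
    stop(sprintf("pairs line %d: %s chromosome '%s' not in genome layout",
                 line_no[bad], side, chrom[bad]))
  }
  oob <- pos1based < 1 | pos1based > len
  if (any(oob)) {
    bad <- which(oob)[1]
    stop(sprintf("pairs line %d: %s position %s out of bounds for %s",
                 line_no[bad], side, format(pos1based[bad], scientific = FALSE),
                 chrom[bad]))
  }
  invisible(TRUE)
}

empty_contact_records <- function() {
  tibble(
    read_id = character(), rna_gene_id = character(),
    rna_chrom = character(), rna_pos = numeric(), rna_strand = character(),
    dna_chrom = character(), dna_pos = numeric(), dna_strand = character(),
    annotation_class = character(), sample_id = character()
  )
}

#' Write contact records to a pairs-style file
#'
#' Inverse of [read_pairs()]: internal 0-based positions are written
#' 1-based. `read_pairs(write_pairs(x))` reproduces `x` field for field.
#'
#' @param records Contact-record tibble (see [read_pairs()]).
#' @param path Output path.
#' @param assembly Genome assembly tag written in the header.
#' @param sort If `TRUE`, records are sorted by
#'   (`rna_gene_id`, `dna_chrom`, `dna_pos`) before writing.
#' @export
write_pairs <- function(records, path, assembly = "synthetic", sort = FALSE) {
  if (sort && nrow(records) > 0) {
    records <- arrange(records, .data$rna_gene_id, .data$dna_chrom,
                       .data$dna_pos)
  }
  header <- c(
    "## pairs-like text format, RNA side first",
    paste0("#genome_assembly: ", assembly),
    paste0("#columns: ", paste(PAIRS_COLUMNS, collapse = " "))
  )
  body <- character(0)
  if (nrow(records) > 0) {
    body <- paste(records$read_id, records$rna_chrom,
                  format(records$rna_pos + 1, scientific = FALSE, trim = TRUE),
                  records$rna_strand, records$dna_chrom,
                  format(records$dna_pos + 1, scientific = FALSE, trim = TRUE),
                  records$dna_strand, records$rna_gene_id,
                  records$annotation_class, records$sample_id,
                  sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Signed RNA-to-DNA travel distance
#'
#' For cis records (RNA and DNA side on the same chromosome) returns
#' dna_pos - rna_pos in bp; for trans records returns `NA` (the undefined
#' sentinel). Antisymmetric under swapping the RNA and DNA positions.
#'
#' @param records Contact-record tibble.
#' @return Numeric vector of signed distances, `NA` for trans contacts.
#' @export
travel_distance <- function(records) {
  ifelse(records$rna_chrom == records$dna_chrom,
         records$dna_pos - records$rna_pos, NA_real_)
}

#' Genomic contact profile of a single RNA
#'
#' Bins the DNA-side positions of one RNA's contacts into fixed-width
#' windows, producing a bedGraph-style tibble. The sum of the track equals
#' the number of that RNA's records.
#'
#' @param records Contact-record tibble.
#' @param rna_gene_id Gene id of the RNA.
#' @param bin_size Bin width in bp.
#' @param genome A [genome_layout()].
#' @return Tibble with columns `chrom`, `start`, `end`, `count` (non-zero
#'   bins only), ordered by chromosome and start.
#' @export
rna_coverage_track <- function(records, rna_gene_id, bin_size, genome) {
  rec <- records[records$rna_gene_id == rna_gene_id, , drop = FALSE]
  if (nrow(rec) == 0) {
    warning("no records for RNA '", rna_gene_id, "'; returning empty track")
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  count = numeric()))
  }
  bin <- floor(rec$dna_pos / bin_size)
  tab <- count(tibble(chrom = rec$dna_chrom, bin = bin),
               .data$chrom, .data$bin, name = "count")
  len <- chrom_length(genome, tab$chrom)
  tibble(
    chrom = tab$chrom,
    start = tab$bin * bin_size,
    end = pmin((tab$bin + 1) * bin_size, len),
    count = as.numeric(tab$count)
  ) |> arrange(.data$chrom, .data$start)
}

#' Write a coverage track as bedGraph
#' @param track Track tibble from [rna_coverage_track()].
#' @param path Output path.
#' @param name Track name for the bedGraph header line.
#' @export
write_bedgraph <- function(track, path, name = "rna_coverage") {
  header <- sprintf("track type=bedGraph name=\"%s\"", name)
  body <- character(0)
  if (nrow(track) > 0) {
    body <- paste(track$chrom,
                  format(track$start, scientific = FALSE, trim = TRUE),
                  format(track$end, scientific = FALSE, trim = TRUE),
                  format(track$count, scientific = FALSE, trim = TRUE),
                  sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
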
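SMALL_RNA_FAMILIES <- c("snRNA", "snoRNA", "scaRNA", "srpRNA", "scRNA",
                        "rRNA")

#' Dominant transposable-element family per UTL
#'
#' From per-read TE annotations, finds for each unannotated transcribed
#' locus (UTL) the family with the highest read count among labeled
#' reads, and a TE-score equal to that family's reads divided by all of
#' the UTL's reads (unlabeled reads included in the denominator). Ties
#' are broken by the lexicographically smallest family name and logged.
#'
#' @param te_reads Tibble with columns `utl_id`, `read_id`, `family`
#'   (`NA` for unlabeled reads).
#' @return Tibble per UTL: `utl_id`, `te_family` (`NA` if no labeled
#'   reads), `te_score`.
#' @export
dominant_te <- function(te_reads) {
  totals <- count(te_reads, .data$utl_id, name = "n_reads")
  lab <- filter(te_reads, !is.na(.data$family)) |>
    count(.data$utl_id, .data$family, name = "n_fam") |>
    group_by(.data$utl_id) |>
    arrange(dplyr::desc(.data$n_fam), .data$family, .by_group = TRUE) |>
    summarise(
      te_family = .data$family[1],
      n_top = .data$n_fam[1],
      tie = sum(.data$n_fam == .data$n_fam[1]) > 1,
      .groups = "drop"
    )
  if (any(lab$tie)) {
    message(sum(lab$tie), " UTL(s) with tied dominant TE families; ",
            "lexicographically smallest chosen")
  }
  out <- left_join(totals, lab, by = "utl_id")
  tibble(
    utl_id = out$utl_id,
    te_family = out$te_family,
    te_score = ifelse(is.na(out$n_top), 0, out$n_top / out$n_reads)
  )
}

utl_five_prime <- function(utls) {
  ifelse(utls$strand == "+", utls$start, utls$end)
}

#' Tag UTLs with nearby active cis-regulatory elements
#'
#' A UTL is tagged with the nearest cis-regulatory element (CRE) that is
#' active (ATAC-overlapping) in either cell state and whose interval
#' lies within `window` bp of the UTL's strand-aware 5' end. The CRE
#' subtype is taken from the first-state annotation if the CRE is active
#' in that state, otherwise from the second.
#'
#' @param utls Tibble with `utl_id`, `chrom`, `strand`, `start`, `end`.
#' @param cres Tibble with `chrom`, `start`, `end`, `active_es`,
#'   `active_de` (logicals) and `class_es`, `class_de` (or a single
#'   `class` column used for both).
#' @param window Maximum distance (bp) from the 5' end (default 300).
#' @return Tibble per UTL: `utl_id`, `cre_class` (`NA` if none),
#'   `cre_distance`.
#' @export
tag_cre <- function(utls, cres, window = 300) {
  if (!"class_es" %in% colnames(cres)) cres$class_es <- cres$class
  if (!"class_de" %in% colnames(cres)) cres$class_de <- cres$class
  active <- filter(cres, .data$active_es | .data$active_de)
  p5 <- utl_five_prime(utls)
  out_class <- rep(NA_character_, nrow(utls))
  out_dist <- rep(NA_real_, nrow(utls))
  if (nrow(active) > 0) {
    for (i in seq_len(nrow(utls))) {
      same <- active[active$chrom == utls$chrom[i], , drop = FALSE]
      if (nrow(same) == 0) next
      # distance from the 5' point to each interval (0 if inside)
      d <- pmax(same$start - p5[i], p5[i] - same$end, 0)
      j <- which.min(d)
      if (d[j] <= window) {
        out_class[i] <- if (same$active_es[j]) same$class_es[j] else
          same$class_de[j]
        out_dist[i] <- d[j]
      }
    }
  }
  tibble(utl_id = utls$utl_id, cre_class = out_class,
         cre_distance = out_dist)
}

#' Tag candidate readthrough UTLs
#'
#' A UTL is a readthrough candidate when its strand-aware 5' end falls
#' in the oriented window [3' end - upstream, 3' end + downstream] of a
#' gene on the same strand, where "+" offsets run downstream in the
#' gene's direction of transcription (so the window reaches `upstream`
#' bp into the gene body and `downstream` bp past its end).
#'
#' @param utls Tibble with `utl_id`, `chrom`, `strand`, `start`, `end`.
#' @param gene_models Gene-model tibble.
#' @param upstream,downstream Window extents in bp (defaults 200 / 100).
#' @param same_strand Require the UTL to continue the gene's strand
#'   (default `TRUE`); set `FALSE` to accept either strand.
#' @return Logical vector, one per UTL.
#' @export
tag_readthrough <- function(utls, gene_models, upstream = 200,
                            downstream = 100, same_strand = TRUE) {
  p5 <- utl_five_prime(utls)
  lo <- ifelse(gene_models$strand == "+",
               gene_models$end3 - upstream, gene_models$end3 - downstream)
  hi <- ifelse(gene_models$strand == "+",
               gene_models$end3 + downstream, gene_models$end3 + upstream)
  vapply(seq_len(nrow(utls)), function(i) {
    hit <- gene_models$chrom == utls$chrom[i] &
      p5[i] >= lo & p5[i] <= hi
    if (same_strand) hit <- hit & gene_models$strand == utls$strand[i]
    any(hit)
  }, logical(1))
}

#' Tag candidate antisense UTLs
#'
#' A UTL is an antisense candidate when the fraction of its length
#' covered by opposite-strand gene bodies (union across genes) is at
#' least `min_overlap`.
#'
#' @param utls Tibble with `utl_id`, `chrom`, `strand`, `start`, `end`.
#' @param gene_models Gene-model tibble.
#' @param min_overlap Minimum overlap fraction (default 0.10).
#' @return Logical vector, one per UTL.
#' @export
tag_antisense <- function(utls, gene_models, min_overlap = 0.10) {
  vapply(seq_len(nrow(utls)), function(i) {
    anti <- gene_models[gene_models$chrom == utls$chrom[i] &
                          gene_models$strand != utls$strand[i], ,
                        drop = FALSE]
    if (nrow(anti) == 0) return(FALSE)
    cov <- IRanges::reduce(IRanges(anti$start + 1, anti$end))
    ov <- IRanges::intersect(cov, IRanges(utls$start[i] + 1, utls$end[i]))
    sum(IRanges::width(ov)) >= min_overlap * (utls$end[i] - utls$start[i])
  }, logical(1))
}

#' Priority-rule classification of UTLs
#'
#' Applies the seven-class priority rules to pre-computed tags; the
#' first matching rule wins: (1) dominant tRNA family with TE-score >
#' 0.10; (2) dominant small-RNA family (snRNA, snoRNA, scaRNA, srpRNA,
#' scRNA, rRNA) with TE-score > 0.10; (3) readthrough; (4) CRE-derived;
#' (5) TE-score > 0.50 (repeat-derived, keeping the dominant family);
#' (6) antisense; (7) intergenic.
#'
#' @param tags Tibble with columns `utl_id`, `te_family`, `te_score`,
#'   `cre_class`, `readthrough`, `antisense`.
#' @return `tags` with columns `class` and `subtype` added; every UTL
#'   receives exactly one class.
#' @export
classify_utl <- function(tags) {
  cls <- character(nrow(tags))
  sub <- rep(NA_character_, nrow(tags))
  for (i in seq_len(nrow(tags))) {
    fam <- tags$te_family[i]
    score <- tags$te_score[i]
    if (!is.na(fam) && fam == "tRNA" && score > 0.10) {
      cls[i] <- "tRNA-derived"
    } else if (!is.na(fam) && fam %in% SMALL_RNA_FAMILIES && score > 0.10) {
      cls[i] <- "snRNA-derived"
    } else if (isTRUE(tags$readthrough[i])) {
      cls[i] <- "readthrough"
    } else if (!is.na(tags$cre_class[i])) {
      cls[i] <- "CRE-derived"
      sub[i] <- tags$cre_class[i]
    } else if (!is.na(fam) && score > 0.50) {
      cls[i] <- "repeat-derived"
      sub[i] <- fam
    } else if (isTRUE(tags$antisense[i])) {
      cls[i] <- "antisense"
    } else {
      cls[i] <- "intergenic"
    }
  }
  mutate(tags, class = cls, subtype = sub)
}

#' Tag and classify UTLs in one pass
#'
#' @param utls Tibble with `utl_id`, `chrom`, `strand`, `start`, `end`.
#' @param te_reads Per-read TE annotations (see [dominant_te()]).
#' @param cres CRE table (see [tag_cre()]).
#' @param gene_models Gene-model tibble.
#' @param cre_window,readthrough_upstream,readthrough_downstream,min_antisense_overlap
#'   Rule parameters.
#' @return Classified tag tibble from [classify_utl()].
#' @export
classify_utls <- function(utls, te_reads, cres, gene_models,
                          cre_window = 300, readthrough_upstream = 200,
                          readthrough_downstream = 100,
                          min_antisense_overlap = 0.10) {
  te <- dominant_te(te_reads)
  tags <- left_join(tibble(utl_id = utls$utl_id), te, by = "utl_id")
  tags$te_score[is.na(tags$te_score)] <- 0
  cre <- tag_cre(utls, cres, window = cre_window)
  tags <- left_join(tags, cre, by = "utl_id")
  tags$readthrough <- tag_readthrough(utls, gene_models,
                                      upstream = readthrough_upstream,
                                      downstream = readthrough_downstream)
  tags$antisense <- tag_antisense(utls, gene_models,
                                  min_overlap = min_antisense_overlap)
  classify_utl(tags)
}
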
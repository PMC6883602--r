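# Exon1--intron--exon2 gene structures, annotation transfer and CDS splicing.
# Coordinates are 1-based inclusive amplicon positions, matching the report
# tables: exon1 may be preceded by an untranslated leader, the intron starts
# with "GT" and ends with "AG", and exon2 ends at the last amplicon base.

#' Construct a gene structure
#'
#' @param exon1,intron,exon2 length-2 integer vectors `c(start, end)` in
#'   1-based inclusive amplicon coordinates; `NULL` for a structure that could
#'   not be annotated.
#' @param total_length amplicon length in bp.
#' @param annotatable logical; unannotatable structures (printed with dashes
#'   in the report tables, typical of pseudogenes) carry no intervals.
#' @return an object of class `gene_structure`.
#' @export
gene_structure <- function(exon1, intron, exon2, total_length,
                           annotatable = TRUE) {
  total_length <- as.integer(total_length)
  if (!annotatable) {
    out <- list(exon1 = NULL, intron = NULL, exon2 = NULL,
                total_length = total_length, annotatable = FALSE)
    class(out) <- "gene_structure"
    return(out)
  }
  exon1 <- as.integer(exon1); intron <- as.integer(intron)
  exon2 <- as.integer(exon2)
  ok <- length(exon1) == 2L && length(intron) == 2L && length(exon2) == 2L &&
    exon1[1] >= 1L && exon1[1] <= exon1[2] &&
    exon1[2] + 1L == intron[1] && intron[1] <= intron[2] &&
    intron[2] + 1L == exon2[1] && exon2[1] <= exon2[2] &&
    exon2[2] == total_length
  if (!ok) {
    input_error("gene structure intervals violate exon1|intron|exon2 adjacency (exon1 %s, intron %s, exon2 %s, total %d)",
                paste(exon1, collapse = "-"), paste(intron, collapse = "-"),
                paste(exon2, collapse = "-"), total_length)
  }
  out <- list(exon1 = exon1, intron = intron, exon2 = exon2,
              total_length = total_length, annotatable = TRUE)
  class(out) <- "gene_structure"
  out
}

#' @export
print.gene_structure <- function(x, ...) {
  if (x$annotatable) {
    cat(sprintf("<gene_structure> %d bp: exon1 %d-%d | intron %d-%d | exon2 %d-%d\n",
                x$total_length, x$exon1[1], x$exon1[2],
                x$intron[1], x$intron[2], x$exon2[1], x$exon2[2]))
  } else {
    cat(sprintf("<gene_structure> %d bp: unannotatable\n", x$total_length))
  }
  invisible(x)
}

structure_from_row <- function(row) {
  gene_structure(c(row$exon1_start, row$exon1_end),
                 c(row$intron_start, row$intron_end),
                 c(row$exon2_start, row$exon2_end),
                 row$total_length %||% row$exon2_end)
}

structure_to_row <- function(s, gene = NA_character_, label = NA_character_) {
  if (s$annotatable) {
    data.frame(gene = gene, label = label,
               exon1_start = s$exon1[1], exon1_end = s$exon1[2],
               intron_start = s$intron[1], intron_end = s$intron[2],
               exon2_start = s$exon2[1], exon2_end = s$exon2[2],
               total_length = s$total_length, stringsAsFactors = FALSE)
  } else {
    data.frame(gene = gene, label = label,
               exon1_start = NA_integer_, exon1_end = NA_integer_,
               intron_start = NA_integer_, intron_end = NA_integer_,
               exon2_start = NA_integer_, exon2_end = NA_integer_,
               total_length = s$total_length, stringsAsFactors = FALSE)
  }
}

#' Transfer exon/intron annotation from a reference haplotype
#'
#' Globally aligns the query amplicon against an annotated reference of the
#' same gene, maps the reference intron boundaries onto the query, then
#' adjusts each boundary by at most `max_shift` bp to the nearest canonical
#' splice dinucleotide (`GT` at the intron start, `AG` at the intron end).
#' If no canonical placement exists within the window, the structure is
#' returned with `annotatable = FALSE`.
#'
#' @param sequence query amplicon (character DNA string).
#' @param ref_sequence annotated reference amplicon of the same gene.
#' @param ref_structure the reference's [gene_structure()].
#' @param max_shift maximum boundary adjustment in bp (default 6).
#' @param scoring alignment scoring parameters (see [pairwise_identity()]).
#' @return a [gene_structure()] for the query.
#' @export
annotate_structure <- function(sequence, ref_sequence, ref_structure,
                               max_shift = 6L, scoring = default_scoring()) {
  if (!inherits(ref_structure, "gene_structure") || !ref_structure$annotatable) {
    input_error("reference structure must be annotatable")
  }
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (identical(sequence, toupper(ref_sequence))) {
    return(ref_structure)   # identity transfer, no alignment needed
  }
  aln <- align_pair(sequence, ref_sequence, "nt", scoring)
  # map each reference position to the closest query position
  qpos <- cumsum(aln$a != "-")
  map <- qpos[aln$b != "-"]          # length == nchar(ref_sequence)
  map[map < 1L] <- 1L

  e1s <- map[ref_structure$exon1[1]]
  is0 <- map[ref_structure$intron[1]]
  ie0 <- map[ref_structure$intron[2]]

  shift_to <- function(pos, motif, at_start) {
    for (s in order(abs(seq(-max_shift, max_shift)), seq(-max_shift, max_shift))) {
      sh <- seq(-max_shift, max_shift)[s]
      p <- pos + sh
      if (at_start) {
        if (p >= 2L && p + 1L <= n && substr(sequence, p, p + 1L) == motif) return(p)
      } else {
        if (p - 1L >= 1L && p < n && substr(sequence, p - 1L, p) == motif) return(p)
      }
    }
    NA_integer_
  }
  is_ <- shift_to(is0, "GT", at_start = TRUE)
  ie <- shift_to(ie0, "AG", at_start = FALSE)

  if (is.na(is_) || is.na(ie) || e1s >= is_ || is_ >= ie || ie >= n) {
    return(gene_structure(NULL, NULL, NULL, n, annotatable = FALSE))
  }
  gene_structure(c(e1s, is_ - 1L), c(is_, ie), c(ie + 1L, n), n)
}

#' Splice the coding region out of an amplicon
#'
#' @param sequence amplicon DNA string.
#' @param structure its annotatable [gene_structure()].
#' @return the exon1 + exon2 substring (coding DNA).
#' @export
splice_cds <- function(sequence, structure) {
  if (!inherits(structure, "gene_structure")) {
    input_error("`structure` must be a gene_structure")
  }
  if (!structure$annotatable) {
    unsupported_error("cannot splice an unannotatable structure")
  }
  if (nchar(sequence) != structure$total_length) {
    input_error("sequence length %d does not match structure total_length %d",
                nchar(sequence), structure$total_length)
  }
  paste0(substr(sequence, structure$exon1[1], structure$exon1[2]),
         substr(sequence, structure$exon2[1], structure$exon2[2]))
}
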
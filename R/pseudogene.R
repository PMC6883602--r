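# Pseudogene calling: scan a spliced coding region for premature in-frame
# stop codons. A copy is a pseudogene when a stop occurs strictly before the
# final complete codon, or when its structure could not be annotated at all.

#' Call a pseudogene from a spliced coding sequence
#'
#' Translates `cds` with the standard nuclear code starting at `frame_offset`
#' and records every stop codon strictly before the final complete codon. A
#' terminal stop is normal termination and does not make a pseudogene. Codons
#' containing IUPAC ambiguity letters are never called stops (conservative
#' rule); codons whose ambiguity could resolve to a stop are reported
#' separately in `ambiguous_stops` with a warning.
#'
#' @param cds coding DNA string (length >= 3).
#' @param frame_offset reading-frame offset, 0, 1 or 2.
#' @return an object of class `pseudogene_call`: list with `is_pseudogene`,
#'   `stop_events` (data.frame: codon_index, cds_position, codon), `reason`
#'   (`"internal_stop"` or `NA`), `n_codons`, `aa` (translation, `*` at
#'   stops, `X` at ambiguous codons) and `ambiguous_stops`.
#' @seealso [unannotatable_pseudogene()] for the structure-based call.
#' @export
call_pseudogene <- function(cds, frame_offset = 0L) {
  if (!frame_offset %in% 0:2) {
    input_error("frame_offset must be 0, 1 or 2 (got %s)",
                paste(frame_offset, collapse = ","))
  }
  cds <- toupper(cds)
  if (nchar(cds) < 3L) input_error("cds must be at least 3 bases long")
  codons <- split_codons(cds, as.integer(frame_offset))
  n_cod <- length(codons)
  internal <- seq_len(max(n_cod - 1L, 0L))
  is_stop <- codons %in% STOP_CODONS

  ambiguous <- which(!codons %in% ALL_CODONS)
  could_stop <- ambiguous[vapply(codons[ambiguous], codon_could_be_stop, logical(1))]
  could_stop <- intersect(could_stop, internal)
  if (length(could_stop)) {
    warning(sprintf("codon(s) %s contain ambiguity letters that could resolve to a stop; not called",
                    paste(could_stop, collapse = ", ")), call. = FALSE)
  }

  hits <- intersect(which(is_stop), internal)
  stop_events <- data.frame(
    codon_index = hits,
    cds_position = frame_offset + (hits - 1L) * 3L + 1L,
    codon = codons[hits],
    stringsAsFactors = FALSE)

  out <- list(
    is_pseudogene = nrow(stop_events) > 0L,
    stop_events = stop_events,
    reason = if (nrow(stop_events) > 0L) "internal_stop" else NA_character_,
    n_codons = n_cod,
    aa = c2s(translate_codons(codons)),
    ambiguous_stops = could_stop)
  class(out) <- "pseudogene_call"
  out
}

codon_could_be_stop <- function(codon) {
  opts <- lapply(s2c(codon), function(b) {
    s2c(Biostrings::IUPAC_CODE_MAP[[b]] %||% b)
  })
  any(apply(expand.grid(opts, stringsAsFactors = FALSE), 1L,
            paste, collapse = "") %in% STOP_CODONS)
}

#' Pseudogene call for a copy whose structure could not be annotated
#'
#' Report tables print dashes for such copies; they are treated as
#' pseudogenes with reason `structure_unannotatable`.
#'
#' @param total_length amplicon length in bp (recorded for reporting).
#' @return a `pseudogene_call` with no stop events.
#' @export
unannotatable_pseudogene <- function(total_length = NA_integer_) {
  out <- list(is_pseudogene = TRUE,
              stop_events = data.frame(codon_index = integer(0),
                                       cds_position = integer(0),
                                       codon = character(0),
                                       stringsAsFactors = FALSE),
              reason = "structure_unannotatable",
              n_codons = NA_integer_, aa = NA_character_,
              ambiguous_stops = integer(0))
  class(out) <- "pseudogene_call"
  out
}

#' @export
print.pseudogene_call <- function(x, ...) {
  if (!x$is_pseudogene) {
    cat(sprintf("<pseudogene_call> functional (%d codons, no internal stop)\n",
                x$n_codons))
  } else if (identical(x$reason, "structure_unannotatable")) {
    cat("<pseudogene_call> pseudogene (structure unannotatable)\n")
  } else {
    cat(sprintf("<pseudogene_call> pseudogene: internal stop at codon %s of %d\n",
                paste(x$stop_events$codon_index, collapse = ", "), x$n_codons))
  }
  invisible(x)
}

#' Map stop events to amplicon coordinates
#'
#' @param call a [call_pseudogene()] result.
#' @param structure the [gene_structure()] the CDS was spliced with.
#' @return the call with an `amplicon_position` column added to `stop_events`
#'   (position of the stop codon's first base in the amplicon).
#' @export
stop_positions_in_amplicon <- function(call, structure) {
  stopifnot(inherits(call, "pseudogene_call"),
            inherits(structure, "gene_structure"))
  if (!structure$annotatable) {
    unsupported_error("cannot map stops through an unannotatable structure")
  }
  e1_len <- structure$exon1[2] - structure$exon1[1] + 1L
  pos <- call$stop_events$cds_position
  call$stop_events$amplicon_position <- ifelse(
    pos <= e1_len,
    structure$exon1[1] + pos - 1L,
    structure$exon2[1] + (pos - e1_len) - 1L)
  call
}

#' Translation up to the first premature stop
#'
#' Used for placing pseudogenes in the amino-acid tree: the translation is
#' truncated to its longest stop-free prefix and flagged.
#'
#' @param call a [call_pseudogene()] result.
#' @return list with `aa` (stop-free prefix) and `truncated` flag.
#' @export
stop_free_prefix <- function(call) {
  stopifnot(inherits(call, "pseudogene_call"))
  aa <- call$aa
  if (is.na(aa)) return(list(aa = "", truncated = TRUE))
  aa <- sub("\\*$", "", aa)          # terminal stop is not informative
  first <- regexpr("*", aa, fixed = TRUE)
  if (first > 0L) {
    list(aa = substr(aa, 1L, first - 1L), truncated = TRUE)
  } else {
    list(aa = aa, truncated = FALSE)
  }
}
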
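# FASTA / TSV / GenBank-flat input and output.
#
# FASTA headers use the dialect `clone_id|gene|taxon`; a plain header is
# accepted when gene and taxon can be looked up in a manifest.

#' Read cloned amplicon records from FASTA
#'
#' @param path FASTA file. Headers are parsed as `clone_id|gene|taxon`; when a
#'   header has no `|` fields, `gene` and `taxon` are taken from `manifest`.
#' @param manifest optional data.frame with columns `clone_id`, `gene`,
#'   `taxon` used for headers lacking the pipe dialect.
#' @return data.frame with columns clone_id, gene, taxon, sequence, length.
#' @export
read_amplicons <- function(path, manifest = NULL) {
  if (!file.exists(path)) input_error("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) input_error("empty FASTA file: %s", path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  parts <- strsplit(headers, "|", fixed = TRUE)
  rows <- lapply(seq_along(headers), function(i) {
    f <- trimws(parts[[i]])
    if (length(f) >= 3L) {
      data.frame(clone_id = f[1], gene = f[2], taxon = f[3],
                 stringsAsFactors = FALSE)
    } else {
      id <- trimws(headers[i])
      hit <- if (!is.null(manifest)) manifest[manifest$clone_id == id, , drop = FALSE]
      if (is.null(hit) || nrow(hit) != 1L) {
        input_error("header '%s' lacks gene/taxon fields and no manifest entry matches",
                    headers[i])
      }
      data.frame(clone_id = id, gene = hit$gene, taxon = hit$taxon,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$sequence <- unname(seqs)
  out$length <- nchar(out$sequence)
  bad <- !is_iupac_dna(out$sequence)
  if (any(bad)) {
    input_error("non-IUPAC characters in record(s): %s",
                paste(out$clone_id[bad], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Write amplicon records as FASTA (`clone_id|gene|taxon` headers)
#'
#' @param records data.frame with clone_id, gene, taxon, sequence.
#' @param path output file.
#' @export
write_amplicons <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(
    records$sequence,
    paste(records$clone_id, records$gene, records$taxon, sep = "|")))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a parental panel as FASTA plus a TSV structure sidecar
#'
#' @param panel a [simulate_parent_panel()] result (or any list with
#'   `haplotypes` and `structures` in the same layout).
#' @param fasta_path,structure_path output files.
#' @export
write_panel <- function(panel, fasta_path, structure_path) {
  set <- Biostrings::BStringSet(setNames(panel$haplotypes$sequence,
                                         panel$haplotypes$label))
  Biostrings::writeXStringSet(set, fasta_path)
  write.table(panel$structures, structure_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Read a panel structure sidecar TSV
#'
#' Columns: gene, label, exon1_start, exon1_end, intron_start, intron_end,
#' exon2_start, exon2_end (total_length optional).
#' @param path TSV file.
#' @export
read_structures <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "label", "exon1_start", "exon1_end", "intron_start",
            "intron_end", "exon2_start", "exon2_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) input_error("structure sidecar lacks column(s): %s",
                                paste(miss, collapse = ", "))
  if (is.null(df$total_length)) df$total_length <- df$exon2_end
  df
}

#' Read a parental reference panel from FASTA + structure sidecar
#'
#' @param fasta_path haplotype FASTA (headers are labels, optionally
#'   `label|gene|role`).
#' @param structure_path structure sidecar TSV (see [read_structures()]).
#' @return a list with `haplotypes` and `structures`, usable wherever a
#'   simulated panel's components are.
#' @export
read_panel <- function(fasta_path, structure_path) {
  set <- Biostrings::readBStringSet(fasta_path)
  if (length(set) == 0L) input_error("empty FASTA file: %s", fasta_path)
  structures <- read_structures(structure_path)
  parts <- strsplit(names(set), "|", fixed = TRUE)
  label <- vapply(parts, function(f) trimws(f[1]), character(1))
  haps <- data.frame(label = label, sequence = toupper(as.character(set)),
                     stringsAsFactors = FALSE)
  m <- match(haps$label, structures$label)
  if (anyNA(m)) {
    input_error("haplotype(s) missing from structure sidecar: %s",
                paste(haps$label[is.na(m)], collapse = ", "))
  }
  haps$gene <- structures$gene[m]
  rownames(haps) <- NULL
  list(haplotypes = haps, structures = structures)
}

#' Write a ground-truth table as TSV
#' @param truth the `truth` component of a [simulate_clone_library()] result.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal GenBank flat-file reader
#'
#' Parses LOCUS / DEFINITION / ACCESSION / ORIGIN blocks of a GenBank flat
#' file into accessioned sequences. Feature tables are ignored: coding
#' regions are derived by this package's own annotation transfer, not from
#' GenBank features.
#'
#' @param path GenBank flat file (possibly multi-record).
#' @return data.frame with columns accession, definition, sequence, length.
#' @export
read_genbank_flat <- function(path) {
  if (!file.exists(path)) input_error("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) input_error("empty GenBank file: %s", path)
  recs <- list(); acc <- NA_character_; def <- character(0)
  in_origin <- FALSE; in_def <- FALSE; seq_chunks <- character(0)
  flush <- function() {
    if (!is.na(acc)) {
      recs[[length(recs) + 1L]] <<- data.frame(
        accession = acc,
        definition = trimws(paste(def, collapse = " ")),
        sequence = toupper(gsub("[^A-Za-z]", "", paste(seq_chunks, collapse = ""))),
        stringsAsFactors = FALSE)
    }
    acc <<- NA_character_; def <<- character(0)
    seq_chunks <<- character(0); in_origin <<- FALSE; in_def <<- FALSE
  }
  for (ln in lines) {
    if (grepl("^LOCUS", ln)) { flush(); next }
    if (grepl("^DEFINITION", ln)) { def <- sub("^DEFINITION\\s+", "", ln); in_def <- TRUE; next }
    if (in_def && grepl("^\\s", ln)) { def <- c(def, trimws(ln)); next } else in_def <- FALSE
    if (grepl("^ACCESSION", ln)) {
      acc <- strsplit(trimws(sub("^ACCESSION", "", ln)), "\\s+")[[1]][1]
      next
    }
    if (grepl("^ORIGIN", ln)) { in_origin <- TRUE; next }
    if (grepl("^//", ln)) { flush(); next }
    if (in_origin) seq_chunks <- c(seq_chunks, ln)
  }
  flush()
  if (!length(recs)) input_error("no records parsed from %s", path)
  out <- do.call(rbind, recs)
  out$length <- nchar(out$sequence)
  out
}
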
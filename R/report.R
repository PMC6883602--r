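# Report tables mirroring the field's presentation: a non-recombinant locus
# table (gene / taxon / locus / size / exon1 / intron / exon2, dashes for
# unannotatable pseudogene rows, "psi" marking pseudogenes), a recombinant
# locus table with "A + B + C" composition strings, a BED-like breakpoint
# table, and pairwise identity tables with "nt/aa" cells, "P" and "-".

fmt_range <- function(s, e) ifelse(is.na(s) | is.na(e), "-",
                                   sprintf("%d-%d", s, e))

#' Format the non-recombinant locus table
#' @param type_tbl the `types` component of a pipeline result.
#' @return data.frame: Genes, Species, Locus, Size_bp, Exon1_bp, Intron_bp,
#'   Exon2_bp, Psi (rows are putative and novel types; unannotatable
#'   pseudogene rows print dashes for the intervals).
#' @export
format_type_table <- function(type_tbl) {
  sub <- type_tbl[type_tbl$class != "recombinant", , drop = FALSE]
  out <- data.frame(
    Genes = sub$gene, Species = sub$taxon, Locus = sub$label,
    Size_bp = sub$total_length,
    Exon1_bp = fmt_range(sub$exon1_start, sub$exon1_end),
    Intron_bp = fmt_range(sub$intron_start, sub$intron_end),
    Exon2_bp = fmt_range(sub$exon2_start, sub$exon2_end),
    Psi = ifelse(sub$is_pseudogene, "psi", ""),
    Support = sub$support,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Format the recombinant locus table
#' @param type_tbl the `types` component of a pipeline result.
#' @return data.frame with composition strings as Locus.
#' @export
format_recombinant_table <- function(type_tbl) {
  sub <- type_tbl[type_tbl$class == "recombinant", , drop = FALSE]
  out <- data.frame(
    Genes = sub$gene, Species = sub$taxon, Locus = sub$composition,
    Size_bp = sub$total_length,
    Exon1_bp = fmt_range(sub$exon1_start, sub$exon1_end),
    Intron_bp = fmt_range(sub$intron_start, sub$intron_end),
    Exon2_bp = fmt_range(sub$exon2_start, sub$exon2_end),
    Psi = ifelse(sub$is_pseudogene, "psi", ""),
    Support = sub$support,
    ChimeraCandidate = ifelse(sub$chimera_candidate, "yes", ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Format the breakpoint table (1-based inclusive segment extents)
#'
#' One row per donor segment of every recombinant type. The span between
#' `segment_end` of one row and `segment_start` of the next is the
#' breakpoint uncertainty interval (no informative site falls inside it).
#'
#' @param type_tbl the `types` component of a pipeline result.
#' @export
format_breakpoint_table <- function(type_tbl) {
  sub <- type_tbl[type_tbl$class == "recombinant", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sub))) {
    comp <- sub$composition_obj[[i]]
    if (is.null(comp)) next
    n_seg <- length(comp$segments)
    bp <- comp$breakpoints
    for (k in seq_len(n_seg)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = sub$gene[i], taxon = sub$taxon[i], type = sub$label[i],
        donor = comp$segments[k],
        segment_start = if (k == 1L) 1L else bp$before_site[k - 1L],
        segment_end = if (k == n_seg) sub$total_length[i] else bp$after_site[k],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), taxon = character(0),
                      type = character(0), donor = character(0),
                      segment_start = integer(0), segment_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise identity report across taxa, one gene per column
#'
#' Mirrors the published identity-table layout: each row is a pair of loci
#' (taxon plus within-gene suffix, e.g. `"SYN-F1 i: SYN-F1 ii"`), each gene
#' a column holding `"nt/aa"`, `"nt/P"` when either member is a pseudogene,
#' or `"-"` when either locus is absent for that gene.
#'
#' @param type_tbl the `types` component of a pipeline result.
#' @return list of class `identity_report`: `long` (gene, id_a, id_b, nt,
#'   aa, cell) and `wide` (pair x gene character matrix).
#' @export
identity_report <- function(type_tbl) {
  sub <- type_tbl[type_tbl$class != "recombinant" & !is.na(type_tbl$cds), ,
                  drop = FALSE]
  sub$suffix <- mapply(function(lab, gene) sub(gene, "", lab, fixed = TRUE),
                       sub$label, sub$gene)
  sub$locus_id <- paste(sub$taxon, sub$suffix)
  genes <- sort(unique(sub$gene))
  long <- list()
  for (g in genes) {
    s <- sub[sub$gene == g, , drop = FALSE]
    if (nrow(s) < 2L) next
    cds <- setNames(s$cds, s$locus_id)
    pg <- setNames(s$is_pseudogene, s$locus_id)
    im <- identity_matrix(cds, pg)
    for (i in seq_len(nrow(s) - 1L)) {
      for (j in (i + 1L):nrow(s)) {
        long[[length(long) + 1L]] <- data.frame(
          gene = g, id_a = s$locus_id[i], id_b = s$locus_id[j],
          nt = im$nt[i, j], aa = im$aa[i, j],
          cell = im$cells[i, j], stringsAsFactors = FALSE)
      }
    }
  }
  long <- if (length(long)) do.call(rbind, long) else
    data.frame(gene = character(0), id_a = character(0), id_b = character(0),
               nt = numeric(0), aa = character(0), cell = character(0),
               stringsAsFactors = FALSE)
  pairs <- unique(long[, c("id_a", "id_b")])
  wide <- matrix("-", nrow(pairs), length(genes),
                 dimnames = list(paste(pairs$id_a, ":", pairs$id_b), genes))
  for (r in seq_len(nrow(long))) {
    wide[paste(long$id_a[r], ":", long$id_b[r]), long$gene[r]] <- long$cell[r]
  }
  out <- list(long = long, wide = wide)
  class(out) <- "identity_report"
  out
}

#' @export
print.identity_report <- function(x, ...) {
  cat(sprintf("<identity_report> %d pair(s) x %d gene(s)\n",
              nrow(x$wide), ncol(x$wide)))
  invisible(x)
}

#' Write all report files of a pipeline result
#'
#' Writes `types.tsv`, `recombinants.tsv`, `breakpoints.tsv`,
#' `identity_long.tsv`, `identity_wide.tsv`, `summary.tsv` and, when a clade
#' check ran, `tree.nwk` and `clades.tsv`. Output is deterministic for a
#' fixed input.
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  w(result$tables$types, "types.tsv")
  w(result$tables$recombinants, "recombinants.tsv")
  w(result$tables$breakpoints, "breakpoints.tsv")
  w(result$tables$identity$long, "identity_long.tsv")
  wide <- data.frame(pair = rownames(result$tables$identity$wide),
                     result$tables$identity$wide, check.names = FALSE,
                     stringsAsFactors = FALSE)
  w(wide, "identity_wide.tsv")
  w(result$summary$counts, "summary.tsv")
  if (!is.null(result$clade)) {
    ape::write.tree(result$clade$tree, file.path(out_dir, "tree.nwk"))
    w(data.frame(gene = names(result$clade$per_gene),
                 recovered = unname(result$clade$per_gene),
                 stringsAsFactors = FALSE), "clades.tsv")
  }
  invisible(out_dir)
}

#' Re-read a written locus table
#'
#' Round-trip counterpart of [format_type_table()] /
#' [format_recombinant_table()]: parses the range strings back into
#' coordinate columns.
#'
#' @param path a `types.tsv` or `recombinants.tsv` written by
#'   [write_reports()].
#' @export
read_type_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(Psi = "character"))
  parse_range <- function(x, which) {
    out <- matrix(NA_integer_, length(x), 2L)
    ok <- x != "-" & !is.na(x)
    parts <- strsplit(x[ok], "-", fixed = TRUE)
    out[ok, ] <- t(vapply(parts, function(p) as.integer(p[1:2]), integer(2)))
    out[, which]
  }
  for (col in c("Exon1_bp", "Intron_bp", "Exon2_bp")) {
    base <- sub("_bp", "", tolower(col))
    df[[paste0(base, "_start")]] <- parse_range(df[[col]], 1L)
    df[[paste0(base, "_end")]] <- parse_range(df[[col]], 2L)
  }
  df
}
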
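# Analysis-side alignment utilities: a centre-star panel aligner (also the
# fallback when MAFFT is unavailable), a joint multiple aligner used by the
# classification pipeline, and query projection helpers. All independent of
# the simulator's own bookkeeping.

#' Align a haplotype panel to common coordinates
#'
#' Centre-star multiple alignment: the longest haplotype (ties: first) is the
#' centre; every other member is globally aligned to it and insertions
#' relative to the centre are merged into shared gap columns. For panels
#' without indels (equal-length haplotypes differing by substitutions only)
#' this reduces to stacking the sequences unchanged. Haplotype panels of one
#' gene are typically >90% identical, where centre-star alignment is exact in
#' practice.
#'
#' @param sequences named character vector of haplotype sequences (names are
#'   the donor labels).
#' @return object of class `hap_panel`: list with `aligned` (character
#'   matrix, rows = haplotypes), `labels`, `center` (label of the centre
#'   sequence) and `sequences`.
#' @export
align_panel <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    input_error("panel sequences must be named with donor labels")
  }
  if (anyDuplicated(names(sequences))) {
    input_error("duplicate donor labels in panel")
  }
  sequences <- toupper(sequences)
  labels <- names(sequences)
  center <- labels[which.max(nchar(sequences))]

  if (length(unique(nchar(sequences))) == 1L &&
      length(sequences) >= 1L) {
    m <- do.call(rbind, lapply(sequences, s2c))
    rownames(m) <- labels
    out <- list(aligned = m, labels = labels, center = center,
                sequences = sequences)
    class(out) <- "hap_panel"
    return(out)
  }

  cseq <- sequences[[center]]
  nc <- nchar(cseq)
  others <- setdiff(labels, center)
  # per member: character vector over centre positions plus insertions keyed
  # by the centre position they follow (0 = before the first)
  per <- list()
  per[[center]] <- list(chars = s2c(cseq), ins = list())
  for (lab in others) {
    aln <- align_pair(sequences[[lab]], cseq, "nt")
    cpos <- cumsum(aln$b != "-")
    chars <- rep("-", nc)
    sel <- aln$b != "-"
    chars[cpos[sel]] <- aln$a[sel]
    ins <- list()
    if (any(!sel)) {
      runs <- rle(sel)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(!runs$values)) {
        after <- if (starts[r] == 1L) 0L else cpos[starts[r] - 1L]
        ins[[as.character(after)]] <- c2s(aln$a[starts[r]:ends[r]])
      }
    }
    per[[lab]] <- list(chars = chars, ins = ins)
  }

  keys <- sort(unique(as.integer(unlist(lapply(per, function(h) names(h$ins))))))
  width <- setNames(integer(length(keys)), keys)
  for (h in per) {
    for (key in names(h$ins)) width[key] <- max(width[key], nchar(h$ins[[key]]))
  }
  rows <- vapply(labels, function(lab) {
    h <- per[[lab]]
    out <- character(0)
    last <- 0L
    for (key in names(width)) {
      p <- as.integer(key)
      if (p >= last + 1L) out <- c(out, h$chars[(last + 1L):p][seq_len(max(p - last, 0L))])
      insert <- h$ins[[key]] %||% ""
      out <- c(out, s2c(paste0(insert,
                               c2s(rep("-", width[key] - nchar(insert))))))
      last <- max(last, p)
    }
    if (last < nc) out <- c(out, h$chars[(last + 1L):nc])
    c2s(out)
  }, character(1))
  m <- do.call(rbind, lapply(rows, s2c))
  rownames(m) <- labels
  out <- list(aligned = m, labels = labels, center = center,
              sequences = sequences)
  class(out) <- "hap_panel"
  out
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d haplotype(s) x %d column(s); centre %s\n",
              nrow(x$aligned), ncol(x$aligned), x$center))
  invisible(x)
}

as_hap_panel <- function(panel) {
  if (inherits(panel, "hap_panel")) return(panel)
  if (is.matrix(panel)) {
    if (is.null(rownames(panel))) input_error("panel matrix must have row labels")
    seqs <- apply(panel, 1L, function(r) c2s(r[r != "-"]))
    out <- list(aligned = panel, labels = rownames(panel),
                center = rownames(panel)[1], sequences = seqs)
    class(out) <- "hap_panel"
    return(out)
  }
  if (is.character(panel)) return(align_panel(panel))
  input_error("cannot interpret panel of class %s", class(panel)[1])
}

# Joint multiple alignment of a set of sequences. Equal-length sets are
# stacked directly (substitution-only variation needs no alignment). Mixed
# lengths go through MAFFT when available -- a joint MSA places every
# sequence consistently, which pairwise projections cannot guarantee in
# alignment-ambiguous indel windows -- and fall back to the centre-star
# aligner otherwise.
align_sequences_msa <- function(sequences) {
  sequences <- toupper(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    input_error("sequences must carry unique names")
  }
  if (length(unique(nchar(sequences))) == 1L) {
    m <- do.call(rbind, lapply(sequences, s2c))
    rownames(m) <- names(sequences)
    return(m)
  }
  if (nzchar(Sys.which("mafft"))) {
    return(run_mafft(sequences))
  }
  warning("mafft not found on PATH; falling back to centre-star alignment",
          call. = FALSE)
  align_panel(sequences)$aligned
}

run_mafft <- function(sequences) {
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  # write with positional names; restore the real names afterwards
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(sequences,
                                    sprintf("s%04d", seq_along(sequences)))),
    fin)
  status <- system2("mafft", c("--auto", "--quiet", shQuote(fin)),
                    stdout = fout, stderr = FALSE)
  if (!identical(status, 0L)) input_error("mafft failed with status %s", status)
  out <- Biostrings::readBStringSet(fout)
  out <- out[order(names(out))]
  m <- do.call(rbind, lapply(as.character(out), function(x) s2c(toupper(x))))
  rownames(m) <- names(sequences)
  m
}

# Project a query sequence onto the panel's column space. Placement must be
# CONSISTENT with how the rows themselves were placed, or independent gap
# choices in alignment-ambiguous windows fabricate mismatches. Three cases:
# a query identical to a panel member reuses that member's row; a query of
# matching length against a gapless panel is stacked directly (the identity
# placement the rows use); anything else is aligned to the centre sequence,
# exactly as the rows were. Query insertions relative to the centre cannot
# be placed and are dropped. Returns the gapped query row plus the true
# query coordinate of each column.
project_query <- function(query, panel) {
  panel <- as_hap_panel(panel)
  query <- toupper(query)
  m <- panel$aligned
  chars <- rep("-", ncol(m))
  qpos <- rep(NA_integer_, ncol(m))

  hit <- match(query, panel$sequences)
  if (!is.na(hit)) {
    row <- m[hit, ]
    cols <- which(row != "-")
    chars[cols] <- row[cols]
    qpos[cols] <- seq_along(cols)
    return(list(chars = chars, query_pos = qpos, anchor = panel$labels[hit]))
  }
  if (nchar(query) == ncol(m) && !any(m == "-")) {
    chars <- s2c(query)
    qpos <- seq_len(ncol(m))
    return(list(chars = chars, query_pos = qpos, anchor = panel$center))
  }

  cseq <- panel$sequences[[panel$center]]
  center_cols <- which(m[panel$center, ] != "-")
  aln <- align_pair(query, cseq, "nt")
  cpos <- cumsum(aln$b != "-")
  qfull <- cumsum(aln$a != "-")   # true query coordinate per alignment row
  sel <- aln$b != "-"
  got <- rep("-", nchar(cseq))
  got[cpos[sel]] <- aln$a[sel]
  gotpos <- rep(NA_integer_, nchar(cseq))
  placed <- sel & aln$a != "-"
  gotpos[cpos[placed]] <- qfull[placed]
  chars[center_cols] <- got
  qpos[center_cols] <- gotpos
  list(chars = chars, query_pos = qpos, anchor = panel$center)
}
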
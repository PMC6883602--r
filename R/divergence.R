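# Pairwise nucleotide / amino-acid identity over coding regions (with the
# "P" pseudogene marker and the dash convention of the report tables), and a
# neighbour-joining clade-partition check on amino-acid p-distances.

#' Percent identity between two sequences
#'
#' Global alignment (default scoring: match +1, mismatch -1, gap open -5,
#' gap extend -1), then identity = identical columns / columns where both
#' sequences have a residue, x100, rounded half-up to one decimal. At the
#' amino-acid level the marker `"P"` is returned when either input is a
#' pseudogene: a truncated product has no comparable protein sequence.
#'
#' @param a,b sequences (DNA for `level = "nt"`; for `level = "aa"`, coding
#'   DNA translated internally, or protein if `translated = TRUE`).
#' @param level `"nt"` or `"aa"`.
#' @param pseudo_a,pseudo_b [call_pseudogene()] results (or logical flags)
#'   consulted at the amino-acid level.
#' @param scoring list(match, mismatch, gap_open, gap_ext).
#' @param include_gaps if `TRUE`, gap columns enter the denominator
#'   (sensitivity variant; the default excludes them).
#' @param translated set `TRUE` when `a`/`b` are already amino acids.
#' @return numeric percent identity with one decimal, or the character
#'   `"P"` for pseudogene pairs at the amino-acid level.
#' @export
pairwise_identity <- function(a, b, level = c("nt", "aa"),
                              pseudo_a = NULL, pseudo_b = NULL,
                              scoring = default_scoring(),
                              include_gaps = FALSE,
                              translated = FALSE) {
  level <- match.arg(level)
  if (!nzchar(a) || !nzchar(b)) input_error("empty sequence in identity computation")
  is_pg <- function(p) {
    if (is.null(p)) return(FALSE)
    if (inherits(p, "pseudogene_call")) return(p$is_pseudogene)
    isTRUE(p)
  }
  if (level == "aa") {
    if (is_pg(pseudo_a) || is_pg(pseudo_b)) return("P")
    if (!translated) {
      a <- c2s(translate_codons(split_codons(a)))
      b <- c2s(translate_codons(split_codons(b)))
    }
    aln <- align_pair(a, b, "aa", scoring)
  } else {
    aln <- align_pair(a, b, "nt", scoring)
  }
  both <- aln$a != "-" & aln$b != "-"
  denom <- if (include_gaps) length(aln$a) else sum(both)
  if (denom == 0L) return(0)
  round_half_up(100 * sum(aln$a == aln$b & both) / denom, 1L)
}

#' Identity matrix over the sequence types of one gene
#'
#' @param cds named character vector of coding sequences (names identify the
#'   types, e.g. `"COC i"`).
#' @param pseudo named logical vector (or list of [call_pseudogene()]
#'   results) marking pseudogene types; amino-acid cells involving them
#'   print `"P"`.
#' @param scoring,include_gaps see [pairwise_identity()].
#' @return list of class `identity_matrix` with `nt` (numeric matrix), `aa`
#'   (character matrix, numbers or `"P"`), and `cells` (character matrix of
#'   `"nt/aa"` strings, diagonal included).
#' @export
identity_matrix <- function(cds, pseudo = NULL, scoring = default_scoring(),
                            include_gaps = FALSE) {
  n <- length(cds)
  if (n < 2L) input_error("identity_matrix needs at least two types")
  ids <- names(cds)
  if (is.null(ids)) input_error("cds must be named")
  if (is.null(pseudo)) pseudo <- setNames(rep(FALSE, n), ids)
  is_pg <- vapply(ids, function(i) {
    p <- pseudo[[i]]
    if (inherits(p, "pseudogene_call")) p$is_pseudogene else isTRUE(p)
  }, logical(1))

  nt <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  aa <- matrix(NA_character_, n, n, dimnames = list(ids, ids))
  aa_seq <- vapply(cds, function(s) c2s(translate_codons(split_codons(s))),
                   character(1))
  for (i in seq_len(n)) {
    nt[i, i] <- 100
    aa[i, i] <- if (is_pg[i]) "P" else "100.0"
    for (j in seq_len(n)[-seq_len(i)]) {
      v <- pairwise_identity(cds[[i]], cds[[j]], "nt", scoring = scoring,
                             include_gaps = include_gaps)
      nt[i, j] <- nt[j, i] <- v
      w <- if (is_pg[i] || is_pg[j]) "P" else
        sprintf("%.1f", pairwise_identity(aa_seq[[i]], aa_seq[[j]], "aa",
                                          scoring = scoring,
                                          include_gaps = include_gaps,
                                          translated = TRUE))
      aa[i, j] <- aa[j, i] <- w
    }
  }
  cells <- matrix(sprintf("%.1f/%s", nt, aa), n, n, dimnames = list(ids, ids))
  out <- list(nt = nt, aa = aa, cells = cells)
  class(out) <- "identity_matrix"
  out
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat("<identity_matrix>\n")
  print(x$cells, quote = FALSE)
  invisible(x)
}

#' Amino-acid p-distance matrix
#'
#' p-distance = proportion of differing residues among columns where both
#' sequences carry one, after pairwise global alignment.
#'
#' @param aa named character vector of amino-acid sequences.
#' @param scoring alignment scoring.
#' @return symmetric numeric matrix.
#' @export
aa_p_distance <- function(aa, scoring = default_scoring()) {
  n <- length(aa)
  d <- matrix(0, n, n, dimnames = list(names(aa), names(aa)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      id <- pairwise_identity(aa[[i]], aa[[j]], "aa", scoring = scoring,
                              translated = TRUE)
      d[i, j] <- d[j, i] <- 1 - id / 100
    }
  }
  d
}

#' Clade-partition check by neighbour joining
#'
#' Builds a neighbour-joining tree on amino-acid p-distances and asks, for
#' each gene group, whether some edge bipartition of the unrooted tree
#' separates exactly that group -- an alignment-light stand-in for a full
#' Bayesian phylogeny when the question is only whether gene families form
#' clean clades. Pseudogene members should be supplied as their longest
#' stop-free translation prefix (see [stop_free_prefix()]); they are kept in
#' the tree.
#'
#' @param aa named character vector of amino-acid sequences (>= 3).
#' @param groups character/factor of gene-group membership, parallel to `aa`.
#' @param anchors optional logical vector marking the per-group anchor
#'   sequence (e.g. the zebrafish orthologue); when given, `anchor_ok`
#'   verifies each recovered group contains exactly one anchor.
#' @return list of class `clade_check`: `n_groups_recovered`, `per_gene`
#'   (named logical), `anchor_ok`, `tree` (an [ape::phylo]), `dist`.
#' @export
clade_partition_check <- function(aa, groups, anchors = NULL) {
  if (length(aa) < 3L) input_error("clade check needs at least 3 sequences")
  if (length(groups) != length(aa)) {
    input_error("`groups` must parallel `aa`")
  }
  if (is.null(names(aa))) names(aa) <- paste0("s", seq_along(aa))
  groups <- as.character(groups)
  d <- aa_p_distance(aa)
  tree <- ape::nj(as.dist(d))
  tips <- tree$tip.label

  parts <- ape::prop.part(tree)
  part_sets <- lapply(parts, function(p) sort(tips[p]))
  all_tips <- sort(tips)

  gene_names <- unique(groups)
  recovered <- vapply(gene_names, function(g) {
    members <- sort(names(aa)[groups == g])
    if (length(members) == length(tips)) return(TRUE)
    if (length(members) == 1L) return(TRUE)   # a single tip is trivially separable
    complement <- setdiff(all_tips, members)
    any(vapply(part_sets, function(p)
      identical(p, members) || identical(p, complement), logical(1)))
  }, logical(1))

  anchor_ok <- NA
  if (!is.null(anchors)) {
    anchor_ok <- all(vapply(gene_names[recovered], function(g) {
      sum(anchors[groups == g]) == 1L
    }, logical(1)))
  }
  out <- list(n_groups_recovered = sum(recovered),
              per_gene = recovered,
              anchor_ok = anchor_ok,
              tree = tree, dist = d)
  class(out) <- "clade_check"
  out
}

#' @export
print.clade_check <- function(x, ...) {
  cat(sprintf("<clade_check> %d/%d gene group(s) recovered as clades; anchors %s\n",
              x$n_groups_recovered, length(x$per_gene),
              if (is.na(x$anchor_ok)) "not checked"
              else if (x$anchor_ok) "ok" else "violated"))
  invisible(x)
}
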
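# Collapse clone libraries into distinct sequence types and assign the
# field's labels: roman numerals for maternal-like copies (i, ii, iii, ...),
# "-BSB" for paternal-derived copies, "-1"/"-2" for novel haplotypes.

#' Collapse clones of one gene and taxon into sequence types
#'
#' Identical sequences are grouped first, then low-support groups are
#' consolidated iteratively: a group with support below `min_support` is
#' absorbed into the closest group of at least its own support within
#' `merge_radius` mismatches (global-alignment edit distance) -- the
#' PCR/sequencing error filter that motivates sequencing 20--30 clones per
#' gene. Absorption is vetoed when the small group looks like a mosaic
#' rather than an error copy: at least two of its mismatches against the
#' absorbing group sit at positions where both conflicting bases are carried
#' by credible groups (support >= `min_support`) -- the signature of an
#' informative site between co-amplified haplotypes. A variant whose
#' deviations are random bases carried by no credible group is PCR error;
#' one whose deviations are shared alleles is a putative recombinant and is
#' kept for classification.
#'
#' The consensus of a merged group is the support-weighted majority base per
#' aligned column, ties going to the dominant member, so scattered errors
#' vote each other out. Isolated low-support groups are kept (they surface
#' later as novel or recombinant types).
#'
#' @param records data.frame of amplicon records (one gene + taxon).
#' @param min_support groups at or above this support are never absorbed.
#' @param merge_radius maximum mismatch distance for absorption.
#' @return data.frame of class `sequence_types`: gene, taxon, consensus,
#'   support, members (semicolon-joined clone ids), sorted by descending
#'   support then consensus.
#' @export
collapse_clones <- function(records, min_support = 2L, merge_radius = 6L) {
  if (is.null(records) || nrow(records) == 0L) {
    input_error("no records to collapse")
  }
  if (length(unique(records$gene)) != 1L || length(unique(records$taxon)) != 1L) {
    input_error("collapse_clones expects records of a single gene and taxon")
  }
  if (min_support < 1L) input_error("min_support must be >= 1")
  if (merge_radius < 0L) input_error("merge_radius must be >= 0")

  seqs <- toupper(records$sequence)
  groups <- split(seq_len(nrow(records)), seqs)
  grp <- lapply(seq_along(groups), function(k) {
    list(consensus = names(groups)[k],
         seqs = names(groups)[k],            # unique member sequences
         weights = length(groups[[k]]),      # parallel clone counts
         members = records$clone_id[groups[[k]]])
  })

  canonical_order <- function(g) {
    order(-vapply(g, function(x) sum(x$weights), numeric(1)),
          vapply(g, `[[`, character(1), "consensus"))
  }

  aln_cache <- new.env(parent = emptyenv())
  getchars <- function(x) {
    key <- paste0("#", x)
    v <- aln_cache[[key]]
    if (is.null(v)) {
      v <- s2c(x)
      aln_cache[[key]] <- v
    }
    v
  }
  base_counts <- function(x) {
    key <- paste0("bc#", x)
    v <- aln_cache[[key]]
    if (is.null(v)) {
      ch <- getchars(x)
      v <- vapply(DNA_BASES, function(b) sum(ch == b), numeric(1))
      aln_cache[[key]] <- v
    }
    v
  }
  dist_capped <- function(a, b) {
    la <- nchar(a); lb <- nchar(b)
    if (abs(la - lb) > merge_radius) return(Inf)
    if (la == lb) {
      h <- sum(getchars(a) != getchars(b))
      if (h <= merge_radius) return(h)
      if (h > 4L * merge_radius) return(Inf)
    }
    # edit distance >= half the base-composition displacement; skip the
    # expensive alignment for clearly distant pairs and cache the rest
    if (sum(abs(base_counts(a) - base_counts(b))) / 2 > merge_radius) {
      return(Inf)
    }
    key <- if (a < b) paste(a, b, sep = "\r\r") else paste(b, a, sep = "\r\r")
    v <- aln_cache[[key]]
    if (is.null(v)) {
      v <- utils::adist(a, b)[1, 1]
      aln_cache[[key]] <- v
    }
    v
  }

  # greedy consolidation: in each pass, walk the small groups from the
  # bottom of the canonical order (they sort last) and absorb each into the
  # closest eligible group unless the donor-evidence veto fires; repeat
  # until stable
  # one merge per iteration, preferring established absorbers (support >=
  # min_support) over small-small nucleation so that the scattered error
  # copies of one haplotype coalesce around a single nucleus
  repeat {
    grp <- grp[canonical_order(grp)]
    support <- vapply(grp, function(x) sum(x$weights), numeric(1))
    cons <- vapply(grp, `[[`, character(1), "consensus")
    small <- which(support < min_support)
    if (!length(small)) break
    # allele evidence for the veto comes from "solid" groups only: their
    # consensus carries no member errors (identical members, or a strict
    # majority at every column). The evidence strings are the groups'
    # dominant members -- stable across merges, so alignments cache.
    is_solid <- support >= min_support &
      (vapply(grp, function(x) length(x$seqs) == 1L, logical(1)) |
         support >= 2L * min_support - 1L)
    dominant <- vapply(grp, function(x)
      x$seqs[order(-x$weights, x$seqs)[1]], character(1))
    solid <- dominant[is_solid]
    # candidate merges: (i small, j earlier in canonical order), ranked by
    # established-target first, then distance, then target support
    cand <- NULL
    for (i in small) {
      js <- seq_len(i - 1L)
      if (!length(js)) next
      d <- vapply(js, function(j) dist_capped(cons[i], cons[j]), numeric(1))
      js <- js[d <= merge_radius]
      if (!length(js)) next
      cand <- rbind(cand, data.frame(i = i, j = js, d = d[d <= merge_radius],
                                     established = support[js] >= min_support))
    }
    if (is.null(cand)) break
    cand <- cand[order(-cand$established, cand$d, -support[cand$j], cand$i), ,
                 drop = FALSE]
    merged <- FALSE
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (mosaic_veto(cons[i], cons[j], setdiff(solid, dominant[i]),
                      target_solid = is_solid[j], cache = aln_cache,
                      proxy = dominant[j])) next
      grp[[j]]$seqs <- c(grp[[j]]$seqs, grp[[i]]$seqs)
      grp[[j]]$weights <- c(grp[[j]]$weights, grp[[i]]$weights)
      grp[[j]]$members <- c(grp[[j]]$members, grp[[i]]$members)
      uw <- tapply(grp[[j]]$weights, grp[[j]]$seqs, sum)
      grp[[j]]$consensus <- majority_consensus(
        names(uw), as.vector(uw),
        refs = setdiff(solid, c(dominant[i], dominant[j])),
        cache = aln_cache)
      grp <- grp[-i]
      merged <- TRUE
      break
    }
    if (!merged) break
  }

  out <- do.call(rbind, lapply(grp, function(x) {
    data.frame(gene = records$gene[1], taxon = records$taxon[1],
               consensus = x$consensus, support = sum(x$weights),
               members = paste(sort(x$members), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$support, out$consensus), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sequence_types", "data.frame")
  out
}

# Mismatch distance capped at `radius`: pairs whose lengths differ by more
# than `radius` cannot be within it (every unmatched base counts); for
# equal-length pairs the substitution (Hamming) distance is used; only
# near-equal lengths need a full edit-distance alignment.
mismatch_distance <- function(a, b, radius) {
  la <- nchar(a); lb <- nchar(b)
  if (abs(la - lb) > radius) return(Inf)
  if (la == lb) {
    h <- sum(s2c(a) != s2c(b))
    if (h <= radius) return(h)
    # a substitution count above the radius can only be beaten by indels
    if (h <= 4L * radius) return(utils::adist(a, b)[1, 1])
    return(Inf)
  }
  utils::adist(a, b)[1, 1]
}

# TRUE when >= 2 mismatches of `small` against `target` look like real
# allelic variation rather than error: at such a position BOTH conflicting
# bases are carried by solid groups (the target's own base counts when the
# target itself is solid) -- the signature of an informative site between
# co-amplified haplotypes, i.e. of a mosaic. A random error base is carried
# by no solid group, so error copies (even compared against other error
# copies) fail the test and are absorbed.
mosaic_veto <- function(small, target, solid, target_solid = FALSE,
                        need = 2L, cache = NULL, proxy = target) {
  if (!length(solid)) return(FALSE)
  # projections are keyed on `proxy` (the target group's stable dominant
  # member): the evolving consensus differs from it only by substitutions,
  # so the same coordinates apply whenever the lengths agree
  if (nchar(proxy) != nchar(target)) proxy <- target
  project <- function(x) {
    if (nchar(x) == nchar(target)) return(s2c(x))
    project_onto(x, proxy, cache)
  }
  sa <- project(small)
  ta <- s2c(target)
  mism <- which(sa != "-" & sa != ta)
  if (length(mism) < need) return(FALSE)
  s_cred <- rep(FALSE, length(mism))
  t_cred <- rep(isTRUE(target_solid), length(mism))
  for (dseq in solid) {
    dchar <- project(dseq)[mism]
    s_cred <- s_cred | dchar == sa[mism]
    t_cred <- t_cred | dchar == ta[mism]
    if (sum(s_cred & t_cred) >= need) return(TRUE)
  }
  sum(s_cred & t_cred) >= need
}

# chars of `x` laid out over `target` coordinates ("-" where unaligned);
# results cached per (x, target) pair within one collapse run
project_onto <- function(x, target, cache = NULL) {
  if (nchar(x) == nchar(target)) return(s2c(x))
  key <- paste(x, target, sep = "\r")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  da <- align_pair(x, target, "nt")
  chars <- rep("-", nchar(target))
  sel <- da$b != "-"
  chars[cumsum(da$b != "-")[sel]] <- da$a[sel]
  if (!is.null(cache)) cache[[key]] <- chars
  chars
}

# Support-weighted majority base per column of pairwise alignments of each
# member sequence to the dominant (highest-weight) sequence; majority gaps
# drop the column. Tied columns (e.g. a two-member group where each member
# carries its own errors) are resolved toward a base carried by one of the
# `refs` haplotypes -- related copies almost always share the true base at
# an error position -- and fall back to the dominant member's base.
majority_consensus <- function(seqs, weights, refs = NULL, cache = NULL) {
  if (length(seqs) == 1L) return(seqs)
  dom <- order(-weights, seqs)[1]
  ref <- seqs[dom]
  n <- nchar(ref)
  ref_mat <- NULL
  pick <- function(winners, dom_base, j) {
    if (length(winners) == 1L) return(winners)
    if (!is.null(refs) && length(refs)) {
      if (is.null(ref_mat)) {
        ref_mat <<- do.call(rbind, lapply(refs, project_onto, target = ref,
                                          cache = cache))
      }
      hit <- intersect(winners, ref_mat[, j])
      if (length(hit) == 1L) return(hit)
    }
    if (dom_base %in% winners) dom_base else winners[1]
  }
  if (all(nchar(seqs) == n)) {   # substitution-only members: vote per column
    mat <- do.call(rbind, lapply(seqs, s2c))
    cons <- vapply(seq_len(n), function(j) {
      tab <- tapply(weights, mat[, j], sum)
      winners <- names(tab)[tab == max(tab)]
      pick(winners, mat[dom, j], j)
    }, character(1))
    return(c2s(cons))
  }
  counts <- matrix(0, nrow = 5L, ncol = n,
                   dimnames = list(c(DNA_BASES, "-"), NULL))
  for (k in seq_along(seqs)) {
    if (seqs[k] == ref) {
      chars <- s2c(ref)
      idx <- cbind(match(chars, rownames(counts)), seq_len(n))
    } else {
      aln <- align_pair(seqs[k], ref, "nt")
      refpos <- cumsum(aln$b != "-")
      sel <- aln$b != "-"
      chars <- aln$a[sel]
      chars[!chars %in% rownames(counts)] <- "-"
      idx <- cbind(match(chars, rownames(counts)), refpos[sel])
    }
    for (r in seq_len(nrow(idx))) {
      counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + weights[k]
    }
  }
  ref_chars <- s2c(ref)
  cons <- vapply(seq_len(n), function(j) {
    col <- counts[, j]
    winners <- rownames(counts)[col == max(col)]
    pick(winners, ref_chars[j], j)
  }, character(1))
  c2s(cons[cons != "-"])
}

#' Assign haplotype labels against a parental reference panel
#'
#' Each type is matched to every parental reference by full-amplicon
#' nucleotide identity. A type whose best match is a maternal reference at or
#' above `identity_floor` receives that reference's roman-numeral label; when
#' several types claim one label the highest identity wins (ties broken by
#' support, then consensus, and logged) and the remaining maternal-like types
#' get the next roman numerals in order of descending support. The best match
#' to each paternal reference inherits its `-BSB` label. Types below the
#' floor against every reference are novel: `-1`, `-2`, ... in discovery
#' order.
#'
#' @param types a [collapse_clones()] result (one gene).
#' @param parental_refs data.frame with columns label, role
#'   (`"maternal"`/`"paternal"`), sequence (and optionally gene).
#' @param identity_floor percent nucleotide identity separating within-family
#'   haplotypes from novel sequences (default 90).
#' @param ref_identities optional precomputed types x references identity
#'   matrix (percent); computed from panel projections when `NULL`.
#' @return `types` with columns label, origin_class (`maternal-like`,
#'   `paternal-like`, `novel`), matched_ref and ref_identity added.
#' @export
assign_labels <- function(types, parental_refs, identity_floor = 90,
                          ref_identities = NULL) {
  if (is.null(parental_refs) || nrow(parental_refs) == 0L) {
    input_error("parental_refs must be nonempty")
  }
  gene <- types$gene[1]
  n <- nrow(types)
  if (is.null(ref_identities)) {
    refs_panel <- align_panel(setNames(parental_refs$sequence,
                                       parental_refs$label))
    idm <- t(vapply(types$consensus, function(s)
      projection_identity(project_query(s, refs_panel), refs_panel),
      numeric(nrow(parental_refs))))
    dim(idm) <- c(n, nrow(parental_refs))
  } else {
    idm <- ref_identities
    stopifnot(nrow(idm) == n, ncol(idm) == nrow(parental_refs))
  }
  best_j <- apply(idm, 1L, which.max)
  best_id <- idm[cbind(seq_len(n), best_j)]

  label <- rep(NA_character_, n)
  origin <- rep(NA_character_, n)
  matched <- rep(NA_character_, n)

  eligible <- best_id >= identity_floor
  # resolve claims reference by reference: highest identity wins
  for (j in seq_len(nrow(parental_refs))) {
    claimants <- which(eligible & best_j == j)
    if (!length(claimants)) next
    ord <- order(-idm[claimants, j], -types$support[claimants],
                 types$consensus[claimants])
    if (length(claimants) > 1L &&
        idm[claimants[ord[1]], j] == idm[claimants[ord[2]], j]) {
      message(sprintf("label tie for %s resolved by support/consensus order",
                      parental_refs$label[j]))
    }
    winner <- claimants[ord[1]]
    label[winner] <- parental_refs$label[j]
    matched[winner] <- parental_refs$label[j]
    origin[winner] <- if (parental_refs$role[j] == "maternal")
      "maternal-like" else "paternal-like"
  }

  # unclaimed eligible types: new variants of their best-matching parent
  pending <- which(eligible & is.na(label))
  maternal_pending <- pending[parental_refs$role[best_j[pending]] == "maternal"]
  paternal_pending <- setdiff(pending, maternal_pending)

  n_maternal_refs <- sum(parental_refs$role == "maternal")
  next_numeral <- n_maternal_refs + 1L
  for (i in maternal_pending[order(-types$support[maternal_pending],
                                   types$consensus[maternal_pending])]) {
    label[i] <- paste0(gene, roman_label(next_numeral))
    origin[i] <- "maternal-like"
    matched[i] <- parental_refs$label[best_j[i]]
    next_numeral <- next_numeral + 1L
  }
  next_pat <- sum(parental_refs$role == "paternal") + 1L
  for (i in paternal_pending[order(-types$support[paternal_pending],
                                   types$consensus[paternal_pending])]) {
    label[i] <- paste0(gene, "-BSB", next_pat)
    origin[i] <- "paternal-like"
    matched[i] <- parental_refs$label[best_j[i]]
    next_pat <- next_pat + 1L
  }

  # below the floor against every reference: novel, numbered in input order
  novel <- which(!eligible)
  for (k in seq_along(novel)) {
    label[novel[k]] <- paste0(gene, "-", k)
    origin[novel[k]] <- "novel"
  }

  types$label <- label
  types$origin_class <- origin
  types$matched_ref <- matched
  types$ref_identity <- best_id
  types
}

#' Extract a parental reference panel for one gene
#'
#' @param panel a [simulate_parent_panel()] or [read_panel()] result.
#' @param gene gene name.
#' @return data.frame with label, role, sequence (rows of the panel for that
#'   gene; role inferred from the label when absent).
#' @export
parental_refs <- function(panel, gene) {
  h <- panel$haplotypes[panel$haplotypes$gene == gene, , drop = FALSE]
  if (nrow(h) == 0L) input_error("gene '%s' not in panel", gene)
  if (is.null(h$role)) {
    h$role <- ifelse(grepl("-BSB", h$label, fixed = TRUE),
                     "paternal", "maternal")
  }
  rownames(h) <- NULL
  h
}
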
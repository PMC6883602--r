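# Mosaic (recombinant) detection: segment a query against a labelled
# haplotype panel by a penalised minimum-mismatch dynamic programme over
# informative sites, and classify clones as putative / recombinant / novel.

#' Find informative sites of an aligned haplotype panel
#'
#' Informative sites are the alignment columns at which at least two panel
#' haplotypes carry distinct non-gap bases; only there can a segment's donor
#' be identified.
#'
#' @param panel a [align_panel()] result, a gapped character matrix with row
#'   labels, or a named character vector of sequences (aligned on the fly).
#' @return list of class `informative_sites`: `columns` (strictly increasing
#'   alignment column indices) and `bases` (panel base matrix restricted to
#'   those columns).
#' @export
find_informative_sites <- function(panel) {
  panel <- as_hap_panel(panel)
  m <- panel$aligned
  if (nrow(m) < 2L) {
    warning("panel has fewer than two haplotypes; no informative sites",
            call. = FALSE)
    cols <- integer(0)
  } else {
    cols <- which(apply(m, 2L, function(col) {
      b <- col[col != "-"]
      length(unique(b)) >= 2L
    }))
  }
  out <- list(columns = cols,
              bases = m[, cols, drop = FALSE])
  class(out) <- "informative_sites"
  out
}

#' @export
print.informative_sites <- function(x, ...) {
  cat(sprintf("<informative_sites> %d column(s)\n", length(x$columns)))
  invisible(x)
}

#' Segment a query against a haplotype panel
#'
#' Over the panel's informative columns, finds the donor-label path
#' minimising `mismatches + lambda * switches` by dynamic programming (the
#' optimum is global). Consecutive equal labels collapse into segments; any
#' segment with fewer than `min_diag` diagnostic sites against an adjacent
#' donor is merged into whichever neighbour costs fewer extra mismatches.
#' Breakpoints are reported as intervals between informative sites (in query
#' coordinates): the true junction is unidentifiable between diagnostic
#' sites, so a point estimate would be false precision.
#'
#' Tie-breaks, in order: continue the current donor (fewer switches), then
#' the donor earlier in panel order.
#'
#' @param query DNA string.
#' @param panel see [find_informative_sites()].
#' @param lambda switch penalty (>= 0); at `lambda >= #informative sites`
#'   the optimum is the best single donor.
#' @param min_diag minimum diagnostic sites per segment (>= 1).
#' @return object of class `recomb_composition`: `segments` (ordered donor
#'   labels), `breakpoints` (data.frame `after_site`/`before_site` in query
#'   coordinates), `mismatches`, `switches`, `penalized_score`,
#'   `single_donor_score`, `n_informative`.
#' @export
segment_query <- function(query, panel, lambda = 0.5, min_diag = 2L) {
  panel <- as_hap_panel(panel)
  jf <- joint_frame(query, panel$sequences)
  segment_projected(jf$proj, jf$panel, lambda, min_diag)
}

# place query and donors in one joint MSA; returns the donor panel rows and
# the query's projection (its own row, with true query coordinates)
joint_frame <- function(query, sequences, msa = NULL) {
  if (is.null(msa)) {
    msa <- align_sequences_msa(c(setNames(toupper(query), ".query"),
                                 sequences))
  }
  qrow <- msa[".query", ]
  qpos <- cumsum(qrow != "-")
  qpos[qrow == "-"] <- NA_integer_
  panel <- list(aligned = msa[setdiff(rownames(msa), ".query"), ,
                              drop = FALSE],
                labels = setdiff(rownames(msa), ".query"),
                center = setdiff(rownames(msa), ".query")[1],
                sequences = sequences)
  class(panel) <- "hap_panel"
  list(panel = panel,
       proj = list(chars = qrow, query_pos = qpos, anchor = NA_character_))
}

# core of segment_query, reusable with a precomputed projection
segment_projected <- function(proj, panel, lambda = 0.5, min_diag = 2L) {
  if (lambda < 0) input_error("lambda must be >= 0")
  if (min_diag < 1L) input_error("min_diag must be >= 1")
  inf <- find_informative_sites(panel)
  H <- nrow(panel$aligned)
  labels <- panel$labels

  m <- length(inf$columns)
  if (m == 0L || H < 2L) {
    # nothing distinguishes donors; nearest haplotype by overall mismatch
    best <- nearest_donor(proj$chars, panel)
    return(new_composition(best$label, data.frame(), best$mismatches, 0L,
                           best$mismatches, best$mismatches, 0L))
  }

  qb <- proj$chars[inf$columns]
  pb <- inf$bases
  # mismatch cost: 1 only where the query AND the donor both carry a base
  # and the bases differ. Gap columns are missing data, and columns NEAR a
  # gap are masked out entirely: gap placement around indels is
  # alignment-ambiguous, so bases there carry no reliable evidence.
  masked <- gap_adjacent_columns(colSums(panel$aligned == "-") > 0L |
                                   proj$chars == "-")[inf$columns]
  cost <- matrix(0, nrow = H, ncol = m)
  qknown <- qb != "-" & qb != "N" & !masked
  for (h in seq_len(H)) {
    cost[h, ] <- as.numeric(qknown & pb[h, ] != "-" & qb != pb[h, ])
  }

  # DP over (site, donor); prefer continuing, then lower donor index
  score <- matrix(Inf, H, m)
  back <- matrix(0L, H, m)
  score[, 1L] <- cost[, 1L]
  for (j in 2:m) {
    prev <- score[, j - 1L]
    best_prev <- which.min(prev)            # lowest index on ties
    for (h in seq_len(H)) {
      stay <- prev[h]
      sw_idx <- if (best_prev == h) {
        o <- order(prev[-h])[1]
        which(seq_len(H) != h)[o]
      } else best_prev
      switch_cost <- prev[sw_idx] + lambda
      if (stay <= switch_cost) {
        score[h, j] <- stay + cost[h, j]
        back[h, j] <- h
      } else {
        score[h, j] <- switch_cost + cost[h, j]
        back[h, j] <- sw_idx
      }
    }
  }
  end <- which.min(score[, m])
  path <- integer(m)
  path[m] <- end
  for (j in m:2) path[j - 1L] <- back[path[j], j]

  single_scores <- rowSums(cost)
  single_best <- min(single_scores)

  comp <- path_to_composition(path, cost, pb, qb, inf$columns, proj,
                              labels, lambda, min_diag, masked)
  comp$single_donor_score <- single_best
  comp$n_informative <- m
  comp
}

nearest_donor <- function(proj_chars, panel) {
  m <- panel$aligned
  qknown <- proj_chars != "-" & proj_chars != "N"
  mis <- vapply(seq_len(nrow(m)), function(h) {
    sum(qknown & m[h, ] != "-" & proj_chars != m[h, ])
  }, numeric(1))
  best <- which.min(mis)
  list(label = panel$labels[best], mismatches = mis[best])
}

new_composition <- function(segments, breakpoints, mismatches, switches,
                            penalized_score, single_donor_score,
                            n_informative) {
  out <- list(segments = segments, breakpoints = breakpoints,
              mismatches = mismatches, switches = switches,
              penalized_score = penalized_score,
              single_donor_score = single_donor_score,
              n_informative = n_informative)
  class(out) <- "recomb_composition"
  out
}

# collapse a donor path into segments, apply the min_diag post-filter, and
# derive breakpoint intervals in query coordinates
path_to_composition <- function(path, cost, pb, qb, columns, proj, labels,
                                lambda, min_diag,
                                masked = rep(FALSE, length(path))) {
  repeat {
    r <- rle(path)
    n_seg <- length(r$values)
    if (n_seg == 1L) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # diagnostic support of each segment against each adjacent donor
    # (substitution columns only: gap columns carry no evidence)
    pair_diag <- function(a, b, span) {
      sum(pb[a, span] != pb[b, span] &
            pb[a, span] != "-" & pb[b, span] != "-" & !masked[span])
    }
    ok <- rep(TRUE, n_seg)
    for (k in seq_len(n_seg)) {
      span <- starts[k]:ends[k]
      if (k > 1L && pair_diag(r$values[k], r$values[k - 1L], span) < min_diag) {
        ok[k] <- FALSE
      }
      if (k < n_seg && pair_diag(r$values[k], r$values[k + 1L], span) < min_diag) {
        ok[k] <- FALSE
      }
    }
    bad <- which(!ok)
    if (!length(bad)) break
    # merge the weakest segment into the cheaper neighbour
    widths <- r$lengths[bad]
    k <- bad[order(widths)[1]]
    span <- starts[k]:ends[k]
    cand <- c(if (k > 1L) r$values[k - 1L], if (k < n_seg) r$values[k + 1L])
    extra <- vapply(cand, function(h) sum(cost[h, span]), numeric(1))
    path[span] <- cand[order(extra)[1]]
  }

  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mismatches <- sum(cost[cbind(path, seq_along(path))])
  switches <- length(r$values) - 1L

  # query coordinate of an informative column; if the query is gapped there,
  # the closest preceding covered position
  qcoord <- function(j) {
    col <- columns[j]
    repeat {
      p <- proj$query_pos[col]
      if (!is.na(p)) return(p)
      col <- col - 1L
      if (col < 1L) return(0L)
    }
  }
  # a breakpoint interval is bounded by the query-evidenced diagnostic sites
  # of the adjacent donor pair: the last site still matching the left donor
  # where the donors differ, and the first site matching the right donor.
  # Between them the two donors are indistinguishable in this query, so the
  # true junction lies inside the interval.
  breakpoints <- if (switches > 0L) {
    after <- integer(switches); before <- integer(switches)
    qknown <- qb != "-" & qb != "N" & !masked
    for (k in seq_len(switches)) {
      da <- r$values[k]; db <- r$values[k + 1L]
      differ <- pb[da, ] != pb[db, ] & pb[da, ] != "-" & pb[db, ] != "-"
      left_ev <- which(differ & qknown & qb == pb[da, ])
      right_ev <- which(differ & qknown & qb == pb[db, ])
      last_left <- max(left_ev[left_ev <= ends[k]], starts[k])
      first_right <- min(right_ev[right_ev >= starts[k + 1L]], ends[k + 1L])
      after[k] <- qcoord(last_left)
      before[k] <- qcoord(first_right)
    }
    data.frame(after_site = after, before_site = before)
  } else {
    data.frame(after_site = integer(0), before_site = integer(0))
  }
  new_composition(labels[r$values], breakpoints, mismatches, switches,
                  mismatches + lambda * switches, NA_real_, length(path))
}

#' @export
print.recomb_composition <- function(x, ...) {
  cat(sprintf("<recomb_composition> %s\n", paste(x$segments, collapse = " + ")))
  cat(sprintf("  %d mismatch(es), %d switch(es), penalised score %.1f over %d informative site(s)\n",
              x$mismatches, x$switches, x$penalized_score, x$n_informative))
  if (nrow(x$breakpoints)) {
    cat(sprintf("  breakpoint interval(s): %s\n",
                paste(sprintf("(%d, %d]", x$breakpoints$after_site,
                              x$breakpoints$before_site), collapse = ", ")))
  }
  invisible(x)
}

#' Format a composition the way the report tables print loci
#' @param x a `recomb_composition` (or character vector of donor labels).
#' @return e.g. `"HoxA4ai + HoxA4a-BSB + HoxA4ai"`.
#' @export
composition_string <- function(x) {
  segs <- if (inherits(x, "recomb_composition")) x$segments else x
  paste(segs, collapse = " + ")
}

#' Classify a sequence type as putative, recombinant or novel
#'
#' A type is recombinant when the best multi-segment composition beats the
#' best single donor by at least `delta` penalised-score units (and survives
#' the `min_diag` filter); putative when its best single-donor identity
#' reaches `identity_floor`; otherwise novel.
#'
#' @param sequence the type's consensus sequence.
#' @param panel donor panel: parental references plus the taxon's own
#'   non-recombinant types (see [find_informative_sites()] for accepted
#'   forms).
#' @param lambda,min_diag see [segment_query()].
#' @param delta margin by which a mosaic must beat the single-donor score.
#' @param identity_floor percent identity below which a type is novel.
#' @return list of class `clone_class`: `class` (`"putative"`,
#'   `"recombinant"`, `"novel"`), `composition` (for recombinants),
#'   `best_donor`, `best_identity`.
#' @export
classify_clone <- function(sequence, panel, lambda = 0.5, min_diag = 2L,
                           delta = 1, identity_floor = 90) {
  panel <- as_hap_panel(panel)
  if (nrow(panel$aligned) == 0L) input_error("empty donor panel")
  jf <- joint_frame(sequence, panel$sequences)
  classify_projected(jf$proj, jf$panel, lambda, min_diag, delta,
                     identity_floor)
}

# identity of a projected query to each panel row: identical columns over
# columns where both carry a base
projection_identity <- function(proj, panel) {
  m <- panel$aligned
  vapply(seq_len(nrow(m)), function(h) {
    both <- proj$chars != "-" & m[h, ] != "-"
    if (!any(both)) return(0)
    round_half_up(100 * sum(proj$chars == m[h, ] & both) / sum(both), 1L)
  }, numeric(1))
}

classify_projected <- function(proj, panel, lambda = 0.5, min_diag = 2L,
                               delta = 1, identity_floor = 90) {
  ids <- projection_identity(proj, panel)
  best <- which.max(ids)
  best_donor <- panel$labels[best]
  best_identity <- ids[[best]]

  comp <- segment_projected(proj, panel, lambda = lambda, min_diag = min_diag)
  # a genuine mosaic must beat the best single donor by the margin AND
  # explain the query: a heavily diverged sequence whose stray matches can
  # be chained into segments is a novel haplotype, not a recombinant
  mosaic_identity <- if (comp$n_informative > 0L) {
    100 * (1 - comp$mismatches / comp$n_informative)
  } else 100
  is_recomb <- length(comp$segments) >= 2L &&
    (comp$single_donor_score - comp$penalized_score) >= delta &&
    mosaic_identity >= identity_floor

  cls <- if (is_recomb) "recombinant"
  else if (best_identity >= identity_floor) "putative"
  else "novel"
  out <- list(class = cls,
              composition = if (is_recomb) comp else NULL,
              best_donor = best_donor,
              best_identity = best_identity)
  class(out) <- "clone_class"
  out
}

#' @export
print.clone_class <- function(x, ...) {
  cat(sprintf("<clone_class> %s (best donor %s at %.1f%%)\n",
              x$class, x$best_donor, x$best_identity))
  if (!is.null(x$composition)) print(x$composition)
  invisible(x)
}
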
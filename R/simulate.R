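# Synthetic-data generator: parental haplotype panels and hybrid clone
# libraries with recorded ground truth (haplotype of origin, breakpoints,
# planted pseudogene stops).
#
# All randomness is driven by one top-level seed; each gene draws from a
# stream hashed from (seed, gene index, stage), so per-gene output is
# reproducible independently of how many genes are simulated.

#' Simulate a panel of labelled parental haplotypes
#'
#' Generates, per gene, an ancestral exon1--intron--exon2 amplicon (canonical
#' `GT..AG` intron, stop-free coding region, optional untranslated leader) and
#' derives the maternal and paternal haplotypes from it by random substitution
#' (Jukes--Cantor-like: uniform site choice, random distinct base) and
#' intron-only indels. Maternal copies are labelled `{gene}i`, `{gene}ii`, ...;
#' paternal copies `{gene}-BSB`. Substitutions never disturb the splice
#' dinucleotides and never create an in-frame stop; premature stops are planted
#' explicitly in a `pseudogene_fraction` of haplotypes and recorded.
#'
#' A per-gene synthetic outgroup haplotype (`{gene}-anchor`, divergence
#' `ortholog_divergence`) is also emitted for use as the clade-check anchor.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return an object of class `parent_panel`: a list with elements
#'   `haplotypes` (data.frame: gene, label, role, sequence, is_pseudogene,
#'   stop_codon_index, stop_codon), `structures` (one row per haplotype with
#'   1-based inclusive exon1/intron/exon2 coordinates), `alignments` (per-gene
#'   character matrix giving the true multiple alignment of the parental
#'   haplotypes), `anchors` (per-gene outgroup amplicons with their coding
#'   sequence), `genes`, `config` and `seed`.
#' @export
simulate_parent_panel <- function(config, seed = config$seed) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, as.list(config))
  }
  validate_sim_config(config)
  genes <- sprintf("synHox%02d", seq_len(config$n_genes))

  hap_rows <- list(); struct_rows <- list(); aln <- list()
  anchor_rows <- list(); gene_rows <- list()

  for (g in seq_along(genes)) {
    gene <- genes[g]
    out <- with_seed(derive_seed(seed, g, 1L), simulate_gene(gene, config))
    hap_rows[[g]] <- out$haplotypes
    struct_rows[[g]] <- out$structures
    aln[[gene]] <- out$alignment
    anchor_rows[[g]] <- out$anchor
    gene_rows[[g]] <- out$gene_row
  }

  panel <- list(
    haplotypes = do.call(rbind, hap_rows),
    structures = do.call(rbind, struct_rows),
    alignments = aln,
    anchors = do.call(rbind, anchor_rows),
    genes = do.call(rbind, gene_rows),
    config = config,
    seed = as.integer(seed)
  )
  rownames(panel$haplotypes) <- NULL
  rownames(panel$structures) <- NULL
  class(panel) <- "parent_panel"
  panel
}

# ---- one gene ---------------------------------------------------------------

simulate_gene <- function(gene, config) {
  lay <- draw_gene_layout(config)
  anc <- build_ancestor(lay)

  n_mat <- config$maternal_copies_per_gene
  n_pat <- config$paternal_copies_per_gene
  labels <- c(paste0(gene, roman_label(seq_len(n_mat))),
              if (n_pat > 0) paste0(gene, c("-BSB", if (n_pat > 1)
                paste0("-BSB", 2:n_pat))))
  roles <- c(rep("maternal", n_mat), rep("paternal", n_pat))

  # each maternal copy sits at half the configured within-parent divergence
  # from the ancestor so a maternal pair realises ~within_parent_divergence;
  # the paternal copy sits so a maternal/paternal pair realises
  # ~between_parent_divergence.
  rate_mat <- config$within_parent_divergence / 2
  rate_pat <- max(config$between_parent_divergence - rate_mat, rate_mat)

  haps <- vector("list", n_mat + n_pat)
  for (i in seq_along(haps)) {
    rate <- if (roles[i] == "maternal") rate_mat else rate_pat
    haps[[i]] <- mutate_haplotype(anc, rate, config$indel_rate,
                                  config$indel_max_len)
  }

  # plant premature stops
  pg <- runif(length(haps)) < config$pseudogene_fraction
  stop_idx <- rep(NA_integer_, length(haps))
  stop_cod <- rep(NA_character_, length(haps))
  for (i in which(pg)) {
    planted <- plant_premature_stop(haps[[i]], anc)
    haps[[i]] <- planted$hap
    stop_idx[i] <- planted$codon_index
    stop_cod[i] <- planted$stop_codon
  }

  alignment <- build_alignment(haps, anc, labels)
  sequences <- apply(alignment, 1L, function(r) c2s(r[r != "-"]))

  structures <- do.call(rbind, lapply(seq_along(haps), function(i) {
    hap_structure(gene, labels[i], haps[[i]], anc)
  }))
  stopifnot(structures$total_length == nchar(sequences))

  anchor <- mutate_haplotype(anc, config$ortholog_divergence, 0, 0L)
  anchor_seq <- c2s(anchor$chars[anchor$chars != "-"])
  anchor_cds <- c2s(anchor$chars[!is.na(anc$cds_pos)])

  list(
    haplotypes = data.frame(
      gene = gene, label = labels, role = roles, sequence = unname(sequences),
      is_pseudogene = pg, stop_codon_index = stop_idx, stop_codon = stop_cod,
      stringsAsFactors = FALSE),
    structures = structures,
    alignment = alignment,
    anchor = data.frame(
      gene = gene, label = paste0(gene, "-anchor"), sequence = anchor_seq,
      cds = anchor_cds, stringsAsFactors = FALSE),
    gene_row = data.frame(
      gene = gene, leader = lay$leader, exon1_len = lay$exon1_len,
      intron_len = lay$intron_len, exon2_len = lay$exon2_len,
      total_length = lay$total, stringsAsFactors = FALSE)
  )
}

draw_gene_layout <- function(config) {
  r <- config$amplicon_length_range
  leader <- sample1(config$leader_length_range[1]:config$leader_length_range[2])
  exon2_len <- 3L * sample1(60:80)             # >= MIN_EXON_LEN, codon-aligned
  exon1_len <- sample1(250:450)
  exon1_len <- exon1_len - (exon1_len + exon2_len) %% 3L  # CDS a whole number of codons
  target <- sample1(r[1]:r[2])
  intron_len <- max(target - leader - exon1_len - exon2_len, 80L)
  list(leader = leader, exon1_len = exon1_len, intron_len = intron_len,
       exon2_len = exon2_len, total = leader + exon1_len + intron_len + exon2_len)
}

# the ancestor carries the coordinate system: `region` per position, `cds_pos`
# (position within the spliced CDS, NA outside exons), `amp_of_cds` the inverse
build_ancestor <- function(lay) {
  cds <- random_cds((lay$exon1_len + lay$exon2_len) %/% 3L)
  seqc <- c(s2c(random_dna(lay$leader)),
            s2c(substr(cds, 1L, lay$exon1_len)),
            s2c(paste0("GT", random_dna(lay$intron_len - 4L), "AG")),
            s2c(substr(cds, lay$exon1_len + 1L, nchar(cds))))
  region <- rep(c("leader", "exon1", "intron", "exon2"),
                times = c(lay$leader, lay$exon1_len, lay$intron_len, lay$exon2_len))
  cds_pos <- rep(NA_integer_, lay$total)
  exonic <- region %in% c("exon1", "exon2")
  cds_pos[exonic] <- seq_len(sum(exonic))
  intron <- which(region == "intron")
  list(chars = seqc, region = region, cds_pos = cds_pos,
       amp_of_cds = which(exonic),
       splice_guard = c(intron[1:2], intron[length(intron) - 1:0]),
       intron_interior = intron[c(-1, -2, -(length(intron) - 1), -length(intron))],
       layout = lay)
}

# substitutions (i.i.d. per site, random distinct base; exonic substitutions
# never create an in-frame stop, splice dinucleotides protected) plus
# intron-only indels. Haplotypes are kept in ancestor coordinates: `chars`
# ("-" = deleted site) and `ins` (insertions keyed by the ancestor position
# they follow).
mutate_haplotype <- function(anc, sub_rate, indel_rate, indel_max_len) {
  chars <- anc$chars
  n <- length(chars)
  sites <- setdiff(which(runif(n) < sub_rate), anc$splice_guard)
  for (p in sites) {
    alt <- setdiff(DNA_BASES, chars[p])
    if (!is.na(anc$cds_pos[p])) {
      ok <- vapply(alt, function(b) {
        tmp <- chars
        tmp[p] <- b
        !codon_at(tmp, anc, p) %in% STOP_CODONS
      }, logical(1))
      alt <- alt[ok]
      if (length(alt) == 0L) next
    }
    chars[p] <- if (length(alt) == 1L) alt else sample(alt, 1L)
  }

  ins <- list()
  if (indel_rate > 0 && length(anc$intron_interior) > 0L) {
    n_ev <- rbinom(1L, length(anc$intron_interior), indel_rate)
    for (k in seq_len(n_ev)) {
      pos <- sample1(anc$intron_interior)
      len <- sample.int(indel_max_len, 1L)
      if (runif(1) < 0.5) {
        span <- intersect(pos:(pos + len - 1L), anc$intron_interior)
        chars[span] <- "-"
      } else {
        key <- as.character(pos)
        ins[[key]] <- paste0(ins[[key]] %||% "", random_dna(len))
      }
    }
  }
  list(chars = chars, ins = ins)
}

codon_at <- function(chars, anc, p) {
  cp <- anc$cds_pos[p]
  cod <- (cp - 1L) %/% 3L
  c2s(chars[anc$amp_of_cds[cod * 3L + 1:3]])
}

# overwrite one internal codon (not the first, not the last, fully inside one
# exon) with a stop codon
plant_premature_stop <- function(hap, anc) {
  n_cod <- length(anc$amp_of_cds) %/% 3L
  candidates <- setdiff(seq_len(n_cod - 1L), 1L)
  exon1_len <- anc$layout$exon1_len
  # codon fully inside exon 1 or fully inside exon 2
  candidates <- candidates[(candidates * 3L <= exon1_len) |
                             ((candidates - 1L) * 3L + 1L > exon1_len)]
  idx <- if (length(candidates) == 1L) candidates else sample(candidates, 1L)
  stop_codon <- sample(STOP_CODONS, 1L)
  hap$chars[anc$amp_of_cds[(idx - 1L) * 3L + 1:3]] <- s2c(stop_codon)
  list(hap = hap, codon_index = idx, stop_codon = stop_codon)
}

# true multiple alignment of the haplotypes: ancestor positions are shared
# columns; insertions become extra columns (right-padded with gaps)
build_alignment <- function(haps, anc, labels) {
  n <- length(anc$chars)
  keys <- sort(unique(as.integer(unlist(lapply(haps, function(h) names(h$ins))))))
  width <- setNames(integer(length(keys)), keys)
  for (h in haps) {
    for (key in names(h$ins)) {
      width[key] <- max(width[key], nchar(h$ins[[key]]))
    }
  }
  rows <- vapply(haps, function(h) {
    out <- character(0)
    last <- 0L
    for (key in names(width)) {
      p <- as.integer(key)
      out <- c(out, h$chars[(last + 1L):p])
      insert <- h$ins[[key]] %||% ""
      pad <- width[key] - nchar(insert)
      out <- c(out, s2c(paste0(insert, c2s(rep("-", pad)))))
      last <- p
    }
    out <- c(out, if (last < n) h$chars[(last + 1L):n])
    c2s(out)
  }, character(1))
  m <- do.call(rbind, lapply(rows, s2c))
  rownames(m) <- labels
  m
}

hap_structure <- function(gene, label, hap, anc) {
  lay <- anc$layout
  intron_cols <- which(anc$region == "intron")
  realized_intron <- sum(hap$chars[intron_cols] != "-") +
    sum(nchar(unlist(hap$ins)))
  e1s <- lay$leader + 1L
  e1e <- lay$leader + lay$exon1_len
  is_ <- e1e + 1L
  ie <- is_ + realized_intron - 1L
  data.frame(gene = gene, label = label,
             exon1_start = e1s, exon1_end = e1e,
             intron_start = is_, intron_end = ie,
             exon2_start = ie + 1L, exon2_end = ie + lay$exon2_len,
             total_length = ie + lay$exon2_len,
             stringsAsFactors = FALSE)
}

#' @export
print.parent_panel <- function(x, ...) {
  cat(sprintf("<parent_panel> %d gene(s), %d haplotypes (%d pseudogene)\n",
              nrow(x$genes), nrow(x$haplotypes), sum(x$haplotypes$is_pseudogene)))
  invisible(x)
}

# ---- clone libraries --------------------------------------------------------

#' Simulate a hybrid clone library from a parental panel
#'
#' Emits exactly `clone_depth` cloned amplicons per gene. Each clone is either
#' a faithful copy of one parental haplotype or (with probability
#' `recombinant_fraction`) a planted mosaic of 2--4 parental segments joined at
#' junctions drawn uniformly between informative alignment columns, with every
#' segment guaranteed at least 2 diagnostic sites against every other panel
#' haplotype (so donor labels are identifiable in principle).
#' Per-base substitution errors are then applied i.i.d. at `error_rate`.
#' Every planted event is recorded in the returned ground truth.
#'
#' @param panel a [simulate_parent_panel()] result.
#' @param config the [sim_config()] used (gene count must match the panel).
#' @param seed integer seed; defaults to `config$seed`.
#' @param taxon taxon tag stamped on every clone (synthetic tag).
#' @return a list of class `clone_library` with `records` (data.frame:
#'   clone_id, gene, taxon, sequence, length) and `truth` (one row per clone:
#'   origin label or `A + B + C` donor composition, true between-site
#'   breakpoints in clone coordinates, number of planted errors).
#' @export
simulate_clone_library <- function(panel, config, seed = config$seed,
                                   taxon = "SYN") {
  stopifnot(inherits(panel, "parent_panel"))
  validate_sim_config(config)
  if (config$n_genes != nrow(panel$genes)) {
    input_error("panel has %d gene(s) but config$n_genes is %d",
                nrow(panel$genes), config$n_genes)
  }
  rec <- list(); tru <- list()
  for (g in seq_len(nrow(panel$genes))) {
    gene <- panel$genes$gene[g]
    out <- with_seed(derive_seed(seed, g, 2L),
                     simulate_gene_clones(gene, panel, config, taxon))
    rec[[g]] <- out$records
    tru[[g]] <- out$truth
  }
  res <- list(records = do.call(rbind, rec), truth = do.call(rbind, tru))
  rownames(res$records) <- NULL
  rownames(res$truth) <- NULL
  class(res) <- "clone_library"
  res
}

simulate_gene_clones <- function(gene, panel, config, taxon) {
  msa <- panel$alignments[[gene]]
  pool <- rownames(msa)
  # columns usable for planting: every pool member has a base and >= 2 differ
  ungapped <- colSums(msa == "-") == 0L
  distinct <- apply(msa, 2L, function(col) length(unique(col[col != "-"]))) >= 2L
  inf_cols <- which(ungapped & distinct)

  records <- vector("list", config$clone_depth)
  truth <- vector("list", config$clone_depth)
  for (k in seq_len(config$clone_depth)) {
    clone_id <- sprintf("%s_%s_c%03d", taxon, gene, k)
    planted <- NULL
    if (length(pool) >= 2L && length(inf_cols) >= 4L &&
        runif(1) < config$recombinant_fraction) {
      planted <- plant_recombinant(msa, pool, inf_cols, config)
    }
    if (is.null(planted)) {
      donor <- sample(pool, 1L)
      seqc <- msa[donor, ]
      seqc <- seqc[seqc != "-"]
      origin <- donor
      breakpoints <- ""
      n_seg <- 1L
    } else {
      seqc <- planted$chars
      origin <- paste(planted$donors, collapse = " + ")
      breakpoints <- paste(planted$breakpoints, collapse = ",")
      n_seg <- length(planted$donors)
    }
    n_err <- 0L
    if (config$error_rate > 0) {
      hit <- which(runif(length(seqc)) < config$error_rate)
      for (p in hit) {
        seqc[p] <- sample(setdiff(DNA_BASES, seqc[p]), 1L)
      }
      n_err <- length(hit)
    }
    records[[k]] <- data.frame(
      clone_id = clone_id, gene = gene, taxon = taxon,
      sequence = c2s(seqc), length = length(seqc), stringsAsFactors = FALSE)
    truth[[k]] <- data.frame(
      clone_id = clone_id, gene = gene, taxon = taxon, origin = origin,
      n_segments = n_seg, breakpoints = breakpoints, n_errors = n_err,
      stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, records), truth = do.call(rbind, truth))
}

# rejection-sample a mosaic: donors form a walk with adjacent labels distinct;
# cuts fall between informative columns; every segment keeps >= 2 diagnostic
# sites against each adjacent donor. Returns NULL when no valid mosaic is
# found (the clone is then emitted as a pure parental copy).
plant_recombinant <- function(msa, pool, inf_cols, config, min_diag = 2L,
                              max_tries = 200L) {
  m <- length(inf_cols)
  # columns near an indel are alignment-ambiguous and carry no evidence the
  # detection side can use, so diagnostic guarantees must avoid them; the
  # planting buffer is doubled so guaranteed sites stay clear of the
  # detection mask even when the analysis alignment drifts by a few columns
  masked <- gap_adjacent_columns(colSums(msa == "-") > 0L,
                                 buffer = 2L * GAP_BUFFER)
  for (try in seq_len(max_tries)) {
    n_seg <- sample(config$segments_per_recombinant[1]:config$segments_per_recombinant[2], 1L)
    if (n_seg - 1L > m - 1L) next
    donors <- character(n_seg)
    donors[1] <- sample(pool, 1L)
    for (j in 2:n_seg) {
      donors[j] <- sample(setdiff(pool, donors[j - 1L]), 1L)
    }
    cuts <- sort(sample(m - 1L, n_seg - 1L))   # cut after informative site index
    bounds <- c(0L, cuts, m)
    # every segment must be distinguishable from EVERY pool haplotype by at
    # least min_diag sites, otherwise the planted donor label would be
    # unidentifiable in principle and the ground truth untestable
    ok <- TRUE
    for (j in seq_len(n_seg)) {
      span <- inf_cols[(bounds[j] + 1L):bounds[j + 1L]]
      for (h in setdiff(pool, donors[j])) {
        # diagnostic evidence = unmasked substitution columns (both donors
        # carry a base, away from indels)
        d <- sum(msa[donors[j], span] != msa[h, span] &
                   msa[donors[j], span] != "-" & msa[h, span] != "-" &
                   !masked[span])
        if (d < min_diag) {
          ok <- FALSE
          break
        }
      }
      # a middle segment also needs sites differing from BOTH neighbours:
      # sites shared with one neighbour can drift across the boundary, so
      # only doubly-exclusive sites pin the segment down
      if (ok && j > 1L && j < n_seg) {
        d2 <- sum(msa[donors[j], span] != msa[donors[j - 1L], span] &
                    msa[donors[j], span] != msa[donors[j + 1L], span] &
                    msa[donors[j], span] != "-" &
                    msa[donors[j - 1L], span] != "-" &
                    msa[donors[j + 1L], span] != "-" &
                    !masked[span])
        if (d2 < min_diag) ok <- FALSE
      }
      if (!ok) break
    }
    if (!ok) next

    junctions <- integer(n_seg - 1L)   # cut after this alignment column
    for (j in seq_len(n_seg - 1L)) {
      lo <- inf_cols[cuts[j]]
      hi <- inf_cols[cuts[j] + 1L] - 1L
      junctions[j] <- if (lo >= hi) lo else sample(lo:hi, 1L)
    }
    chars <- msa[donors[1L], ]
    prev <- 0L
    for (j in seq_len(n_seg)) {
      to <- if (j < n_seg) junctions[j] else ncol(msa)
      chars[(prev + 1L):to] <- msa[donors[j], (prev + 1L):to]
      prev <- to
    }
    # the planted composition must be the only exact k-segment explanation
    # of the mosaic, else the ground-truth donor labels are unidentifiable
    if (!unique_composition(chars[inf_cols], msa[, inf_cols, drop = FALSE],
                            donors, masked[inf_cols])) next
    keep <- chars != "-"
    clone_pos <- cumsum(keep)
    breakpoints <- clone_pos[junctions]  # junction after this clone base
    return(list(chars = chars[keep], donors = donors,
                breakpoints = breakpoints))
  }
  NULL
}

# TRUE when `donors` is the only sequence of up to length(donors)
# adjacent-distinct labels whose segments can tile the informative sites
# with every site matching its segment's donor: any shorter or equal-length
# exact explanation would make the planted composition unidentifiable
# (explanations with more segments, or with mismatches, always score worse
# under the detection objective given the per-segment diagnostic minima).
unique_composition <- function(mosaic, panel_bases, donors,
                               masked = rep(FALSE, length(mosaic))) {
  H <- nrow(panel_bases)
  m <- length(mosaic)
  k <- length(donors)
  pool <- rownames(panel_bases)
  # compatibility mirrors the detection cost: gap on either side scores 0
  # and masked (indel-adjacent) columns carry no evidence, so only an
  # unmasked base-vs-base difference makes a label infeasible
  mm <- matrix(mosaic, H, m, byrow = TRUE)
  compat <- panel_bases == mm | panel_bases == "-" | mm == "-" |
    matrix(masked, H, m, byrow = TRUE)
  # run[h, j]: end of the maximal compatible run of haplotype h starting at j
  run <- matrix(0L, H, m, dimnames = list(pool, NULL))
  for (h in seq_len(H)) {
    nxt <- 0L
    for (j in m:1) {
      nxt <- if (compat[h, j]) max(nxt, j) else 0L
      run[h, j] <- if (compat[h, j]) {
        if (j < m && compat[h, j + 1L]) run[h, j + 1L] else j
      } else 0L
    }
  }
  feasible <- function(labels) {
    reach <- c(TRUE, rep(FALSE, m))   # reach[j + 1]: first j sites consumed
    for (s in seq_along(labels)) {
      nxt <- rep(FALSE, m + 1L)
      for (j0 in which(reach) - 1L) {
        if (j0 >= m) next
        if (!compat[labels[s], j0 + 1L]) next
        hi <- run[labels[s], j0 + 1L]
        nxt[(j0 + 2L):(hi + 1L)] <- TRUE
      }
      reach <- nxt
      if (!any(reach)) return(FALSE)
    }
    reach[m + 1L]
  }
  # enumerate adjacent-distinct label sequences of length 1..k
  seqs <- lapply(pool, identity)
  for (cand in seqs) if (feasible(cand)) return(FALSE)
  for (s in 2:k) {
    seqs <- unlist(lapply(seqs, function(p) {
      lapply(setdiff(pool, p[length(p)]), function(h) c(p, h))
    }), recursive = FALSE)
    for (cand in seqs) {
      if (identical(cand, donors)) next
      if (feasible(cand)) return(FALSE)
    }
  }
  feasible(donors)
}

#' @export
print.clone_library <- function(x, ...) {
  n_rec <- sum(x$truth$n_segments > 1L)
  cat(sprintf("<clone_library> %d clones over %d gene(s); %d planted mosaic(s)\n",
              nrow(x$records), length(unique(x$records$gene)), n_rec))
  invisible(x)
}
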
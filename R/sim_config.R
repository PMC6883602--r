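#' Simulation configuration for synthetic hybrid clone libraries
#'
#' Bundles and validates every tunable of the synthetic-data generator. The
#' defaults emulate the sampling design of a cloned Hox amplicon survey of a
#' carp x bream hybrid: per gene, two diverged maternal haplotypes plus one
#' paternal haplotype, amplicons of 700--1600 bp spanning exon1--intron--exon2,
#' 30 clones sequenced per gene with a low per-base error rate, a minority of
#' mosaic (recombinant) clones, and occasional pseudogene copies carrying a
#' premature stop codon.
#'
#' @param n_genes number of independent gene families to simulate.
#' @param maternal_copies_per_gene maternal haplotypes per gene (default 2,
#'   the duplicated-gene situation of the maternal parent).
#' @param paternal_copies_per_gene paternal haplotypes per gene (default 1).
#' @param amplicon_length_range inclusive bp range for amplicon length.
#' @param within_parent_divergence expected substitutions/site between the two
#'   maternal haplotypes of one gene.
#' @param between_parent_divergence expected substitutions/site between
#'   maternal and paternal haplotypes of one gene.
#' @param indel_rate intron indel events per intron site per haplotype
#'   (events are 1--`indel_max_len` bp, insertions or deletions, intron only).
#' @param indel_max_len maximum indel event length in bp.
#' @param clone_depth clones sequenced per gene (default 30).
#' @param error_rate per-base substitution error rate applied i.i.d. to every
#'   clone, emulating PCR/sequencing error.
#' @param recombinant_fraction fraction of clones planted as mosaics of
#'   parental segments.
#' @param segments_per_recombinant inclusive range for the number of donor
#'   segments in a planted mosaic (2--4).
#' @param pseudogene_fraction probability that a parental haplotype carries a
#'   planted premature stop codon.
#' @param ortholog_divergence substitutions/site of the per-gene synthetic
#'   outgroup ("anchor") haplotype used by the clade check.
#' @param leader_length_range inclusive bp range of untranslated leader before
#'   exon 1 (report tables show exon 1 need not start at position 1).
#' @param seed default integer seed used when none is passed to the
#'   simulation functions.
#'
#' @return a validated list of class `sim_config`.
#' @seealso [simulate_parent_panel()], [simulate_clone_library()]
#' @export
sim_config <- function(n_genes = 12L,
                       maternal_copies_per_gene = 2L,
                       paternal_copies_per_gene = 1L,
                       amplicon_length_range = c(700L, 1600L),
                       within_parent_divergence = 0.05,
                       between_parent_divergence = 0.10,
                       indel_rate = 0.002,
                       indel_max_len = 6L,
                       clone_depth = 30L,
                       error_rate = 1e-3,
                       recombinant_fraction = 0.1,
                       segments_per_recombinant = c(2L, 4L),
                       pseudogene_fraction = 0.1,
                       ortholog_divergence = 0.25,
                       leader_length_range = c(0L, 90L),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    maternal_copies_per_gene = as.integer(maternal_copies_per_gene),
    paternal_copies_per_gene = as.integer(paternal_copies_per_gene),
    amplicon_length_range = as.integer(amplicon_length_range),
    within_parent_divergence = within_parent_divergence,
    between_parent_divergence = between_parent_divergence,
    indel_rate = indel_rate,
    indel_max_len = as.integer(indel_max_len),
    clone_depth = as.integer(clone_depth),
    error_rate = error_rate,
    recombinant_fraction = recombinant_fraction,
    segments_per_recombinant = as.integer(segments_per_recombinant),
    pseudogene_fraction = pseudogene_fraction,
    ortholog_divergence = ortholog_divergence,
    leader_length_range = as.integer(leader_length_range),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

# Minimum exon length the generator guarantees (exon 2 must hold the 60-aa
# homeodomain, i.e. at least 180 bp).
MIN_EXON_LEN <- 180L

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 1L) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < min) {
      config_error(field, sprintf("must be a single count >= %d", min))
    }
  }
  chk_rate <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      config_error(field, "must be a rate in [0, 1]")
    }
  }
  chk_count("n_genes")
  chk_count("maternal_copies_per_gene")
  chk_count("paternal_copies_per_gene", min = 0L)
  chk_count("clone_depth")
  chk_count("indel_max_len")
  for (f in c("within_parent_divergence", "between_parent_divergence",
              "indel_rate", "error_rate", "recombinant_fraction",
              "pseudogene_fraction", "ortholog_divergence")) {
    chk_rate(f)
  }
  r <- cfg$amplicon_length_range
  if (length(r) != 2L || any(is.na(r)) || r[1] > r[2]) {
    config_error("amplicon_length_range", "must be an increasing bp interval")
  }
  if (r[1] < 3L * MIN_EXON_LEN) {
    config_error("amplicon_length_range",
                 sprintf("minimum must be >= 3x minimum exon length (%d bp)",
                         3L * MIN_EXON_LEN))
  }
  s <- cfg$segments_per_recombinant
  if (length(s) != 2L || any(is.na(s)) || s[1] < 2L || s[2] > 4L || s[1] > s[2]) {
    config_error("segments_per_recombinant", "must be a sub-interval of [2, 4]")
  }
  l <- cfg$leader_length_range
  if (length(l) != 2L || any(is.na(l)) || l[1] < 0L || l[1] > l[2]) {
    config_error("leader_length_range", "must be a non-negative bp interval")
  }
  if (length(cfg$seed) != 1L || is.na(cfg$seed)) {
    config_error("seed", "must be a single integer")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d gene(s); %d maternal + %d paternal copies per gene\n",
              x$n_genes, x$maternal_copies_per_gene, x$paternal_copies_per_gene))
  cat(sprintf("  amplicons %d-%d bp; divergence within/between parents %.3f/%.3f\n",
              x$amplicon_length_range[1], x$amplicon_length_range[2],
              x$within_parent_divergence, x$between_parent_divergence))
  cat(sprintf("  depth %d clones/gene; error %.2g/base; recombinant fraction %.2f; pseudogene fraction %.2f\n",
              x$clone_depth, x$error_rate, x$recombinant_fraction,
              x$pseudogene_fraction))
  invisible(x)
}
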
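# Orchestration: annotate -> collapse -> label -> classify -> identity ->
# clade check -> report tables, over synthetic or user-supplied clone
# libraries. The engine (`analyze_library`) is a pure function of records +
# panel + parameters; `run_pipeline` adds input handling and report files.

#' Analysis parameters for the clone pipeline
#'
#' @param min_support,merge_radius see [collapse_clones()].
#' @param identity_floor see [assign_labels()] / [classify_clone()].
#' @param lambda,min_diag,delta see [segment_query()] / [classify_clone()].
#' @param scoring alignment scoring, see [pairwise_identity()].
#' @param frame_offset reading-frame offset for pseudogene calling.
#' @export
pipeline_params <- function(min_support = 2L, merge_radius = 6L,
                            identity_floor = 90, lambda = 0.5, min_diag = 2L,
                            delta = 1, scoring = default_scoring(),
                            frame_offset = 0L) {
  out <- list(min_support = as.integer(min_support),
              merge_radius = as.integer(merge_radius),
              identity_floor = identity_floor, lambda = lambda,
              min_diag = as.integer(min_diag), delta = delta,
              scoring = scoring, frame_offset = as.integer(frame_offset))
  class(out) <- "pipeline_params"
  out
}

#' Pipeline run configuration
#'
#' Exactly one input mode is active: `"simulate"` (generate a panel and
#' libraries from `sim`), `"fasta"` (clone FASTA plus a parental panel FASTA
#' and structure sidecar) or `"genbank"` (local GenBank flat file plus a
#' manifest mapping accessions to gene/taxon, plus the parental panel).
#'
#' @param mode input mode.
#' @param sim a [sim_config()] (simulate mode).
#' @param taxa taxon tags to simulate (simulate mode).
#' @param fasta clone FASTA path(s) (fasta mode).
#' @param manifest optional manifest data.frame or TSV path with clone_id,
#'   gene, taxon (fasta/genbank modes).
#' @param genbank local GenBank flat-file path (genbank mode; records are
#'   matched to the manifest by accession).
#' @param panel_fasta,panel_structures parental panel files (fasta/genbank
#'   modes).
#' @param params a [pipeline_params()].
#' @param out_dir directory for report files (`NULL` = no files written).
#' @param seed integer seed for simulate mode.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @export
run_config <- function(mode = c("simulate", "fasta", "genbank"),
                       sim = sim_config(), taxa = "SYN-F1",
                       fasta = NULL, manifest = NULL, genbank = NULL,
                       panel_fasta = NULL, panel_structures = NULL,
                       params = pipeline_params(), out_dir = NULL,
                       seed = NULL, log_level = "info") {
  mode <- match.arg(mode)
  if (mode == "fasta") {
    if (is.null(fasta)) config_error("fasta", "fasta mode needs clone FASTA path(s)")
    for (f in c(fasta, panel_fasta, panel_structures)) {
      if (!is.null(f) && !file.exists(f)) config_error("fasta", sprintf("file not found: %s", f))
    }
    if (is.null(panel_fasta) || is.null(panel_structures)) {
      config_error("panel_fasta", "fasta mode needs a parental panel FASTA and structure sidecar")
    }
  }
  if (mode == "genbank") {
    if (is.null(genbank) || !file.exists(genbank)) {
      config_error("genbank", "genbank mode needs an existing local flat file")
    }
    if (is.null(manifest)) {
      config_error("manifest", "genbank mode needs an accession manifest")
    }
    if (is.null(panel_fasta) || is.null(panel_structures)) {
      config_error("panel_fasta", "genbank mode needs a parental panel FASTA and structure sidecar")
    }
  }
  if (is.character(manifest) && length(manifest) == 1L && file.exists(manifest)) {
    manifest <- read.delim(manifest, stringsAsFactors = FALSE)
  }
  out <- list(mode = mode, sim = sim, taxa = taxa, fasta = fasta,
              manifest = manifest, genbank = genbank,
              panel_fasta = panel_fasta, panel_structures = panel_structures,
              params = params, out_dir = out_dir,
              seed = as.integer(seed %||% sim$seed), log_level = log_level)
  class(out) <- "run_config"
  out
}

pipe_log <- function(config_level, level, msg, ...) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  if (levels[[config_level %||% "info"]] >= levels[[level]]) {
    message(sprintf(msg, ...))
  }
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage [%s]: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the clone analysis over a library and a parental panel
#'
#' The engine behind [run_pipeline()]: for every taxon and gene, collapses
#' clones into sequence types, labels them against the parental references,
#' classifies them as putative / recombinant / novel (the donor panel for
#' recombinant detection is the parental references plus the taxon's own
#' non-recombinant types), annotates exon/intron structure, splices coding
#' regions, calls pseudogenes, computes identity matrices, and (when anchors
#' are available) runs the clade-partition check.
#'
#' @param records amplicon records (data.frame: clone_id, gene, taxon,
#'   sequence).
#' @param panel parental panel with `haplotypes` and `structures` (from
#'   [simulate_parent_panel()] or [read_panel()]).
#' @param params a [pipeline_params()].
#' @param anchors optional data.frame(gene, label, cds) of per-gene outgroup
#'   coding sequences for the clade check (simulate mode supplies the
#'   panel's synthetic anchors).
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return list of class `pipeline_result`: `summary` (a `lineage_summary`),
#'   `types` (per-type table with class, structure, pseudogene call),
#'   `tables` (report data.frames: types, recombinants, breakpoints,
#'   identity), `clade` (a `clade_check` or `NULL`), `params`.
#' @export
analyze_library <- function(records, panel, params = pipeline_params(),
                            anchors = NULL, log_level = "info") {
  genes <- unique(records$gene)
  taxa <- unique(records$taxon)
  all_types <- list()

  for (taxon in taxa) {
    for (gene in genes) {
      sub <- records[records$gene == gene & records$taxon == taxon, , drop = FALSE]
      if (nrow(sub) == 0L) next
      refs <- run_stage("label", parental_refs(panel, gene))
      types <- run_stage("collapse",
                         collapse_clones(sub, params$min_support, params$merge_radius))
      ref_seqs <- setNames(refs$sequence, refs$label)
      # one joint alignment of references + types keeps every placement
      # mutually consistent for labelling and classification
      joint <- run_stage("classify", align_sequences_msa(
        c(ref_seqs, setNames(types$consensus,
                             sprintf(".t%03d", seq_len(nrow(types)))))))
      frames <- lapply(seq_len(nrow(types)), function(i)
        frame_from_joint(joint, sprintf(".t%03d", i), refs$label, ref_seqs))
      idm <- t(vapply(frames, function(jf)
        projection_identity(jf$proj, jf$panel), numeric(nrow(refs))))
      dim(idm) <- c(nrow(types), nrow(refs))
      types <- run_stage("label",
                         assign_labels(types, refs, params$identity_floor,
                                       ref_identities = idm))
      types <- run_stage("classify",
                         classify_types(types, refs, params, joint))
      types <- run_stage("annotate",
                         annotate_types(types, refs, panel, params))
      pipe_log(log_level, "debug", "%s %s: %d type(s)", taxon, gene, nrow(types))
      all_types[[paste(taxon, gene)]] <- types
    }
  }
  type_tbl <- do.call(rbind, all_types)
  rownames(type_tbl) <- NULL

  identity <- run_stage("identity", identity_report(type_tbl))
  clade <- NULL
  if (!is.null(anchors)) {
    clade <- run_stage("clade_check", clade_check_from_types(type_tbl, anchors))
  }
  summary <- lineage_summary(type_tbl, params$min_support)
  tables <- list(types = format_type_table(type_tbl),
                 recombinants = format_recombinant_table(type_tbl),
                 breakpoints = format_breakpoint_table(type_tbl),
                 identity = identity)
  out <- list(summary = summary, types = type_tbl, tables = tables,
              clade = clade, params = params)
  class(out) <- "pipeline_result"
  out
}

# extract one type's view from the joint alignment: its own row becomes
# the query projection, the named donor rows become the panel
frame_from_joint <- function(joint, query_row, donor_rows, donor_seqs) {
  qrow <- joint[query_row, ]
  qpos <- cumsum(qrow != "-")
  qpos[qrow == "-"] <- NA_integer_
  panel <- list(aligned = joint[donor_rows, , drop = FALSE],
                labels = donor_rows, center = donor_rows[1],
                sequences = donor_seqs)
  class(panel) <- "hap_panel"
  list(panel = panel,
       proj = list(chars = qrow, query_pos = qpos, anchor = NA_character_))
}

# two-pass classification: first against the parental references alone to
# find the taxon's non-recombinant types, then against references plus
# those types. A type whose label claimed a parental reference stays
# represented by the reference itself; other types are excluded from their
# own donor panel (a sequence always explains itself). All placements come
# from one joint alignment (`joint`) of references + types, so they are
# mutually consistent.
classify_types <- function(types, refs, params, joint = NULL) {
  ref_seqs <- setNames(refs$sequence, refs$label)
  n <- nrow(types)
  tnames <- sprintf(".t%03d", seq_len(n))
  if (is.null(joint)) {
    joint <- align_sequences_msa(c(ref_seqs, setNames(types$consensus,
                                                      tnames)))
  }
  pass1 <- vapply(seq_len(n), function(i) {
    jf <- frame_from_joint(joint, tnames[i], refs$label, ref_seqs)
    classify_projected(jf$proj, jf$panel, params$lambda, params$min_diag,
                       params$delta, params$identity_floor)$class
  }, character(1))

  added <- which(pass1 != "recombinant" & !types$label %in% refs$label)

  cls <- character(n)
  comp <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- setdiff(added, i)
    donor_rows <- c(refs$label, tnames[keep])
    donor_seqs <- c(ref_seqs, setNames(types$consensus[keep],
                                       tnames[keep]))
    jf <- frame_from_joint(joint, tnames[i], donor_rows, donor_seqs)
    # donor rows named after types report under their assigned labels
    rownames(jf$panel$aligned) <- jf$panel$labels <-
      c(refs$label, types$label[keep])
    names(jf$panel$sequences) <- c(refs$label, types$label[keep])
    res <- classify_projected(jf$proj, jf$panel, params$lambda,
                              params$min_diag, params$delta,
                              params$identity_floor)
    cls[i] <- res$class
    comp[i] <- list(res$composition)
  }
  types$class <- cls
  types$composition <- vapply(comp, function(x)
    if (is.null(x)) NA_character_ else composition_string(x), character(1))
  types$composition_obj <- comp
  # single-clone mosaics are classic PCR-chimera candidates; flagged,
  # never adjudicated
  types$chimera_candidate <- cls == "recombinant" & types$support == 1L
  types
}

annotate_types <- function(types, refs, panel, params) {
  structs <- panel$structures
  n <- nrow(types)
  srows <- vector("list", n)
  pcalls <- vector("list", n)
  for (i in seq_len(n)) {
    ref_label <- types$matched_ref[i]
    if (is.na(ref_label)) {  # novel type: annotate against the closest reference
      ids <- vapply(refs$sequence, function(s)
        pairwise_identity(types$consensus[i], s, "nt"), numeric(1))
      ref_label <- refs$label[which.max(ids)]
    }
    ref_row <- structs[structs$label == ref_label, , drop = FALSE]
    if (nrow(ref_row) == 1L && !is.na(ref_row$exon1_start)) {
      st <- annotate_structure(types$consensus[i],
                               refs$sequence[refs$label == ref_label][1],
                               structure_from_row(ref_row),
                               scoring = params$scoring)
    } else {
      st <- gene_structure(NULL, NULL, NULL, nchar(types$consensus[i]),
                           annotatable = FALSE)
    }
    if (st$annotatable) {
      cds <- splice_cds(types$consensus[i], st)
      pc <- call_pseudogene(cds, params$frame_offset)
      pc <- stop_positions_in_amplicon(pc, st)
      pcalls[[i]] <- pc
      srows[[i]] <- structure_to_row(st, types$gene[i], types$label[i])
      srows[[i]]$cds <- cds
    } else {
      pcalls[[i]] <- unannotatable_pseudogene(nchar(types$consensus[i]))
      srows[[i]] <- structure_to_row(st, types$gene[i], types$label[i])
      srows[[i]]$cds <- NA_character_
    }
  }
  st_tbl <- do.call(rbind, srows)
  types$exon1_start <- st_tbl$exon1_start; types$exon1_end <- st_tbl$exon1_end
  types$intron_start <- st_tbl$intron_start; types$intron_end <- st_tbl$intron_end
  types$exon2_start <- st_tbl$exon2_start; types$exon2_end <- st_tbl$exon2_end
  types$total_length <- nchar(types$consensus)
  types$cds <- st_tbl$cds
  types$is_pseudogene <- vapply(pcalls, `[[`, logical(1), "is_pseudogene")
  types$pseudogene_reason <- vapply(pcalls, function(p)
    p$reason %||% NA_character_, character(1))
  types$pseudogene_call <- pcalls
  types
}

clade_check_from_types <- function(type_tbl, anchors) {
  keep <- type_tbl$class != "recombinant" & !is.na(type_tbl$cds)
  sub <- type_tbl[keep, , drop = FALSE]
  aa <- character(0); groups <- character(0); anchor_flag <- logical(0)
  nm <- character(0)
  for (i in seq_len(nrow(sub))) {
    pc <- sub$pseudogene_call[[i]]
    tr <- stop_free_prefix(pc)
    if (nchar(tr$aa) < 10L) next
    aa <- c(aa, tr$aa)
    groups <- c(groups, sub$gene[i])
    anchor_flag <- c(anchor_flag, FALSE)
    nm <- c(nm, paste(sub$taxon[i], sub$label[i]))
  }
  for (i in seq_len(nrow(anchors))) {
    aa <- c(aa, c2s(translate_codons(split_codons(anchors$cds[i]))))
    groups <- c(groups, anchors$gene[i])
    anchor_flag <- c(anchor_flag, TRUE)
    nm <- c(nm, anchors$label[i])
  }
  if (length(aa) < 3L) return(NULL)
  names(aa) <- make.unique(nm)
  clade_partition_check(aa, groups, anchor_flag)
}

#' Run the full pipeline from a configuration
#'
#' @param config a [run_config()].
#' @return a `pipeline_result` (see [analyze_library()]); in simulate mode
#'   the generating `panel` and per-taxon `library` objects are attached.
#'   When `config$out_dir` is set, report TSVs, the breakpoint table, the
#'   clade tree (Newick) and a machine-readable summary are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "simulate") {
    panel <- run_stage("simulate", simulate_parent_panel(config$sim, config$seed))
    libs <- list()
    for (t in seq_along(config$taxa)) {
      libs[[config$taxa[t]]] <- run_stage("simulate",
        simulate_clone_library(panel, config$sim,
                               derive_seed(config$seed, 1000L, t),
                               taxon = config$taxa[t]))
    }
    records <- do.call(rbind, lapply(libs, `[[`, "records"))
    rownames(records) <- NULL
    anchors <- panel$anchors
  } else if (config$mode == "fasta") {
    panel <- run_stage("read", read_panel(config$panel_fasta, config$panel_structures))
    records <- do.call(rbind, lapply(config$fasta, read_amplicons,
                                     manifest = config$manifest))
    libs <- NULL; anchors <- NULL
  } else {
    panel <- run_stage("read", read_panel(config$panel_fasta, config$panel_structures))
    gb <- run_stage("read", read_genbank_flat(config$genbank))
    mf <- config$manifest
    m <- match(gb$accession, mf$clone_id)
    if (anyNA(m)) {
      input_error("accession(s) missing from manifest: %s",
                  paste(gb$accession[is.na(m)], collapse = ", "))
    }
    records <- data.frame(clone_id = gb$accession, gene = mf$gene[m],
                          taxon = mf$taxon[m], sequence = gb$sequence,
                          length = gb$length, stringsAsFactors = FALSE)
    libs <- NULL; anchors <- NULL
  }

  result <- analyze_library(records, panel, config$params, anchors,
                            config$log_level)
  result$panel <- panel
  result$library <- libs

  if (!is.null(config$out_dir)) {
    run_stage("report", write_reports(result, config$out_dir))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

# ---- summaries --------------------------------------------------------------

#' Summarise types per taxon and gene
#'
#' Counts are reported both raw (every emitted type) and curated
#' (`putative_supported`: putative types seen in at least `min_support`
#' clones). Whether a published locus inventory counts every clone-backed
#' variant or only multi-clone loci is data-dependent; both countings are
#' exposed.
#'
#' @param type_tbl the `types` component of a pipeline result.
#' @param min_support support threshold for the curated counting.
#' @return object of class `lineage_summary`: `counts` (per taxon: putative,
#'   recombinant, novel, pseudogene loci, total) and `labels` (per taxon and
#'   gene, the locus labels present with their class).
#' @export
lineage_summary <- function(type_tbl, min_support = 2L) {
  counts <- do.call(rbind, lapply(split(type_tbl, type_tbl$taxon), function(s) {
    data.frame(taxon = s$taxon[1],
               putative = sum(s$class == "putative"),
               putative_supported = sum(s$class == "putative" &
                                          s$support >= min_support),
               recombinant = sum(s$class == "recombinant"),
               novel = sum(s$class == "novel"),
               pseudogene_loci = sum(s$is_pseudogene),
               total_types = nrow(s),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  stopifnot(counts$putative + counts$recombinant + counts$novel ==
              counts$total_types)
  labels <- type_tbl[, c("taxon", "gene", "label", "class", "support",
                         "is_pseudogene", "composition")]
  out <- list(counts = counts, labels = labels,
              genes = sort(unique(type_tbl$gene)))
  class(out) <- "lineage_summary"
  out
}

#' @export
print.lineage_summary <- function(x, ...) {
  cat("<lineage_summary>\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Compare locus inventories between two generations
#'
#' @param summary_parent,summary_offspring `lineage_summary` objects over
#'   the same gene set.
#' @return list of class `inheritance_report`: `per_gene` (labels retained /
#'   lost / gained) and `retention` (fraction of parental loci retained).
#' @export
compare_lineage_inheritance <- function(summary_parent, summary_offspring) {
  stopifnot(inherits(summary_parent, "lineage_summary"),
            inherits(summary_offspring, "lineage_summary"))
  if (!identical(summary_parent$genes, summary_offspring$genes)) {
    input_error("generation summaries cover different gene sets")
  }
  locus_key <- function(s) {
    ifelse(is.na(s$labels$composition), s$labels$label, s$labels$composition)
  }
  pg <- split(locus_key(summary_parent), summary_parent$labels$gene)
  og <- split(locus_key(summary_offspring), summary_offspring$labels$gene)
  per_gene <- lapply(summary_parent$genes, function(g) {
    p <- unique(pg[[g]] %||% character(0))
    o <- unique(og[[g]] %||% character(0))
    list(gene = g, retained = intersect(p, o),
         lost = setdiff(p, o), gained = setdiff(o, p))
  })
  names(per_gene) <- summary_parent$genes
  n_parent <- sum(lengths(lapply(per_gene, `[[`, "retained"))) +
    sum(lengths(lapply(per_gene, `[[`, "lost")))
  retention <- if (n_parent == 0L) NA_real_ else
    sum(lengths(lapply(per_gene, `[[`, "retained"))) / n_parent
  out <- list(per_gene = per_gene, retention = retention)
  class(out) <- "inheritance_report"
  out
}

#' @export
print.inheritance_report <- function(x, ...) {
  cat(sprintf("<inheritance_report> retention %.3f over %d gene(s)\n",
              x$retention, length(x$per_gene)))
  invisible(x)
}

#' Subsample a parental panel to emulate transmission to the next generation
#'
#' Each haplotype is retained independently with probability `retention`;
#' at least one haplotype per gene always survives.
#'
#' @param panel a [simulate_parent_panel()] result.
#' @param retention transmission probability per haplotype.
#' @param seed integer seed.
#' @return the panel with non-transmitted haplotypes removed.
#' @export
simulate_offspring_panel <- function(panel, retention, seed) {
  stopifnot(inherits(panel, "parent_panel"))
  if (retention < 0 || retention > 1) config_error("retention", "must be in [0, 1]")
  keep <- with_seed(derive_seed(seed, 4L), {
    k <- runif(nrow(panel$haplotypes)) < retention
    for (g in unique(panel$haplotypes$gene)) {
      idx <- which(panel$haplotypes$gene == g)
      if (!any(k[idx])) k[idx[sample.int(length(idx), 1L)]] <- TRUE
    }
    k
  })
  panel$haplotypes <- panel$haplotypes[keep, , drop = FALSE]
  panel$structures <- panel$structures[panel$structures$label %in%
                                         panel$haplotypes$label, , drop = FALSE]
  for (g in names(panel$alignments)) {
    rows <- rownames(panel$alignments[[g]]) %in% panel$haplotypes$label
    panel$alignments[[g]] <- panel$alignments[[g]][rows, , drop = FALSE]
  }
  rownames(panel$haplotypes) <- NULL
  rownames(panel$structures) <- NULL
  panel
}
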
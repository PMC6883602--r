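test_that("simulation is deterministic and conserves ground truth", {
  cfg <- sim_config(n_genes = 2, seed = 7)
  p1 <- simulate_parent_panel(cfg, 7)
  p2 <- simulate_parent_panel(cfg, 7)
  expect_identical(p1, p2)
  l1 <- simulate_clone_library(p1, cfg, 7)
  l2 <- simulate_clone_library(p2, cfg, 7)
  expect_identical(l1, l2)
  # a different seed actually changes the output
  expect_false(identical(p1, simulate_parent_panel(cfg, 8)))

  # one ground-truth entry per clone, clone_depth clones per gene
  expect_equal(nrow(l1$truth), nrow(l1$records))
  expect_setequal(l1$truth$clone_id, l1$records$clone_id)
  expect_true(all(table(l1$records$gene) == cfg$clone_depth))
})

test_that("panel layout follows the configured copy numbers and labels", {
  cfg <- sim_config(n_genes = 3, seed = 2)
  p <- simulate_parent_panel(cfg, 2)
  for (g in p$genes$gene) {
    h <- p$haplotypes[p$haplotypes$gene == g, ]
    expect_equal(nrow(h), 3L)
    expect_identical(h$label, paste0(g, c("i", "ii", "-BSB")))
    expect_identical(h$role, c("maternal", "maternal", "paternal"))
  }
  # canonical splice dinucleotides are planted at every intron boundary
  for (i in seq_len(nrow(p$haplotypes))) {
    s <- p$structures[i, ]
    seqs <- p$haplotypes$sequence[i]
    expect_identical(substr(seqs, s$intron_start, s$intron_start + 1L), "GT")
    expect_identical(substr(seqs, s$intron_end - 1L, s$intron_end), "AG")
    expect_equal(s$total_length, nchar(seqs))
  }
  # ancestral amplicons stay inside the configured length range; haplotype
  # lengths may drift by a few bases through intron indels
  expect_true(all(p$genes$total_length >= cfg$amplicon_length_range[1]))
  expect_true(all(p$genes$total_length <= cfg$amplicon_length_range[2]))
  expect_true(all(abs(nchar(p$haplotypes$sequence) -
                        p$genes$total_length[match(p$haplotypes$gene,
                                                   p$genes$gene)]) <= 30))
})

test_that("zero divergence collapses the maternal pair to identical strings", {
  cfg <- sim_config(n_genes = 2, within_parent_divergence = 0, indel_rate = 0,
                    pseudogene_fraction = 0, seed = 3)
  p <- simulate_parent_panel(cfg, 3)
  for (g in split(p$haplotypes, p$haplotypes$gene)) {
    expect_identical(g$sequence[1], g$sequence[2])
  }
})

test_that("noise-free libraries reproduce parental haplotypes byte-identically", {
  cfg <- sim_config(n_genes = 2, error_rate = 0, recombinant_fraction = 0,
                    seed = 4)
  p <- simulate_parent_panel(cfg, 4)
  l <- simulate_clone_library(p, cfg, 4)
  expect_true(all(l$records$sequence %in% p$haplotypes$sequence))
  expect_true(all(l$truth$n_segments == 1L))
  # origins name real haplotypes and match the emitted sequence
  m <- match(l$truth$origin, p$haplotypes$label)
  expect_false(anyNA(m))
  expect_identical(l$records$sequence, p$haplotypes$sequence[m])
})

test_that("realised maternal divergence matches the configured rate", {
  # Monte-Carlo over replicate genes: mean pairwise mismatch fraction of the
  # two maternal copies must sit within +-10% of the configured 0.05
  cfg <- sim_config(n_genes = 1000, indel_rate = 0, pseudogene_fraction = 0,
                    seed = 10)
  p <- simulate_parent_panel(cfg, 10)
  frac <- vapply(split(p$haplotypes, p$haplotypes$gene), function(h) {
    a <- strsplit(h$sequence[1], "")[[1]]
    b <- strsplit(h$sequence[2], "")[[1]]
    mean(a != b)
  }, numeric(1))
  expect_gt(mean(frac), 0.05 * 0.9)
  expect_lt(mean(frac), 0.05 * 1.1)
})

test_that("per-clone error counts follow the binomial expectation", {
  # L = 1000, error 1e-3, 500 clones -> mean errors/clone ~ 1.0 within 3 SE
  cfg <- sim_config(n_genes = 1, amplicon_length_range = c(1000, 1000),
                    clone_depth = 500, recombinant_fraction = 0,
                    pseudogene_fraction = 0, seed = 12)
  p <- simulate_parent_panel(cfg, 12)
  expect_equal(unique(nchar(p$haplotypes$sequence[p$haplotypes$label ==
    paste0(p$genes$gene[1], "i")])), 1000L)
  l <- simulate_clone_library(p, cfg, 12)
  expected <- 1000 * 1e-3
  se <- sqrt(1000 * 1e-3 * (1 - 1e-3) / 500)
  expect_lt(abs(mean(l$truth$n_errors) - expected), 3 * se)
})

test_that("planted mosaics and stops are re-verifiable against the panel", {
  world <- small_sim(21, n_genes = 3, error_rate = 0, recombinant_fraction = 0.3)
  tr <- world$lib$truth
  rec <- tr[tr$n_segments > 1L, ]
  expect_gt(nrow(rec), 0)
  for (i in seq_len(nrow(rec))) {
    bps <- as.integer(strsplit(rec$breakpoints[i], ",")[[1]])
    expect_length(bps, rec$n_segments[i] - 1L)
    expect_true(all(diff(bps) > 0))          # strictly increasing
    donors <- strsplit(rec$origin[i], " + ", fixed = TRUE)[[1]]
    expect_true(all(donors %in% world$panel$haplotypes$label))
    expect_true(all(donors[-1] != donors[-length(donors)]))
  }
  # planted premature stops translate to * at the recorded codon index
  hp <- world$panel$haplotypes
  st <- world$panel$structures
  for (i in which(hp$is_pseudogene)) {
    s <- hoxclone:::structure_from_row(st[i, ])
    cds <- splice_cds(hp$sequence[i], s)
    call <- call_pseudogene(cds)
    expect_true(call$is_pseudogene)
    expect_true(hp$stop_codon_index[i] %in% call$stop_events$codon_index)
  }
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(error_rate = 2), "error_rate",
               class = "hoxclone_config_error")
  expect_error(sim_config(clone_depth = 0), "clone_depth",
               class = "hoxclone_config_error")
  expect_error(sim_config(amplicon_length_range = c(100, 1600)),
               "amplicon_length_range", class = "hoxclone_config_error")
  expect_error(sim_config(segments_per_recombinant = c(2, 9)),
               "segments_per_recombinant", class = "hoxclone_config_error")
  # library generation rejects a panel/config gene-count mismatch
  cfg2 <- sim_config(n_genes = 2, seed = 1)
  cfg3 <- sim_config(n_genes = 3, seed = 1)
  p <- simulate_parent_panel(cfg2, 1)
  expect_error(simulate_clone_library(p, cfg3, 1),
               class = "hoxclone_input_error")
})
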
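make_records <- function(seqs, gene = "g1", taxon = "T") {
  data.frame(clone_id = sprintf("c%03d", seq_along(seqs)), gene = gene,
             taxon = taxon, sequence = seqs, length = nchar(seqs),
             stringsAsFactors = FALSE)
}

test_that("identical clones collapse to a single fully-supported type", {
  seqs <- rep(hoxclone:::random_dna(800), 30)
  types <- collapse_clones(make_records(seqs))
  expect_equal(nrow(types), 1L)
  expect_equal(types$support, 30L)
  expect_identical(types$consensus, seqs[1])
})

test_that("collapse is invariant to clone input order and conserves clones", {
  world <- small_sim(31, n_genes = 1)
  sub <- world$lib$records
  t1 <- collapse_clones(sub)
  set.seed(9)
  t2 <- collapse_clones(sub[sample(nrow(sub)), ])
  expect_identical(t1[, c("consensus", "support", "members")],
                   t2[, c("consensus", "support", "members")])
  expect_equal(sum(t1$support), nrow(sub))
})

test_that("raising min_support never increases the number of types", {
  world <- small_sim(32, n_genes = 1)
  n_types <- vapply(1:4, function(ms)
    nrow(collapse_clones(world$lib$records, min_support = ms)), integer(1))
  expect_true(all(diff(n_types) <= 0))
})

test_that("error clones are absorbed and the consensus votes them out", {
  set.seed(5)
  hapA <- hoxclone:::random_dna(900)
  hapB <- local({  # ~5% diverged sibling
    ch <- strsplit(hapA, "")[[1]]
    at <- sample(900, 45)
    for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  })
  corrupt <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(length(ch), k)
    for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  seqs <- c(rep(hapA, 10), rep(hapB, 8),
            vapply(1:5, function(i) corrupt(hapA, sample(1:2, 1)), ""),
            vapply(1:4, function(i) corrupt(hapB, sample(1:2, 1)), ""))
  types <- collapse_clones(make_records(seqs))
  expect_equal(nrow(types), 2L)
  expect_setequal(types$consensus, c(hapA, hapB))
  expect_equal(sort(types$support), c(12L, 15L))
})

test_that("a low-support mosaic is protected from absorption", {
  set.seed(6)
  hapA <- hoxclone:::random_dna(600)
  chB <- strsplit(hapA, "")[[1]]
  diff_at <- sort(sample(600, 30))
  for (p in diff_at) chB[p] <- sample(setdiff(c("A", "C", "G", "T"), chB[p]), 1)
  hapB <- paste(chB, collapse = "")
  # mosaic: hapA with its last two diagnostic sites taken from hapB --
  # within merge radius of hapA yet donor-supported at 2 positions
  chM <- strsplit(hapA, "")[[1]]
  take <- tail(diff_at, 2)
  chM[take] <- chB[take]
  mosaic <- paste(chM, collapse = "")
  seqs <- c(rep(hapA, 14), rep(hapB, 15), mosaic)
  types <- collapse_clones(make_records(seqs))
  expect_equal(nrow(types), 3L)
  expect_true(mosaic %in% types$consensus)
})

test_that("zero-noise collapse recovers the planted haplotype set exactly", {
  for (seed in 1:5) {
    world <- small_sim(seed, n_genes = 1, error_rate = 0,
                       recombinant_fraction = 0)
    types <- collapse_clones(world$lib$records)
    expect_setequal(types$consensus, world$panel$haplotypes$sequence)
  }
})

test_that("labels follow the reference panel naming scheme", {
  world <- small_sim(33, n_genes = 1, error_rate = 0, recombinant_fraction = 0)
  gene <- world$panel$genes$gene[1]
  refs <- parental_refs(world$panel, gene)
  types <- collapse_clones(world$lib$records)
  types <- assign_labels(types, refs)
  # every type is an exact parental copy, so labels must match exactly
  m <- match(types$consensus, refs$sequence)
  expect_identical(types$label, refs$label[m])
  expect_identical(types$origin_class,
                   ifelse(refs$role[m] == "maternal", "maternal-like",
                          "paternal-like"))
  expect_true(all(types$ref_identity == 100))
})

test_that("new variants get the next roman numeral, distant types go novel", {
  set.seed(7)
  base <- hoxclone:::random_dna(600)
  mutate_n <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(length(ch), n)
    for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  refs <- data.frame(
    label = c("gXi", "gXii", "gX-BSB"),
    role = c("maternal", "maternal", "paternal"),
    sequence = c(base, mutate_n(base, 30), mutate_n(base, 60)),
    stringsAsFactors = FALSE)
  variant <- mutate_n(base, 12)          # ~98% to ref i -> third maternal copy
  novel <- mutate_n(base, 150)           # ~75% to everything -> novel
  types <- data.frame(gene = "gX", taxon = "T",
                      consensus = c(refs$sequence[1], refs$sequence[2],
                                    variant, novel),
                      support = c(10L, 9L, 5L, 4L),
                      members = "x", stringsAsFactors = FALSE)
  out <- assign_labels(types, refs, identity_floor = 90)
  expect_identical(out$label, c("gXi", "gXii", "gXiii", "gX-1"))
  expect_identical(out$origin_class,
                   c("maternal-like", "maternal-like", "maternal-like",
                     "novel"))
  expect_lt(out$ref_identity[4], 90)
})

test_that("degenerate and invalid haplotyping inputs error", {
  expect_error(collapse_clones(make_records("ACGT")[0, ]),
               class = "hoxclone_input_error")
  recs <- rbind(make_records("ACGT", gene = "g1"),
                make_records("ACGT", gene = "g2"))
  expect_error(collapse_clones(recs), class = "hoxclone_input_error")
  types <- collapse_clones(make_records(rep("ACGTACGT", 3)))
  expect_error(assign_labels(types, data.frame()),
               class = "hoxclone_input_error")
})

test_that("noisy libraries recover the planted pair of maternal haplotypes", {
  # two maternal haplotypes, depth 30, error 1e-3: the curated type set
  # (support >= min_support) equals the planted pair in >= 95% of replicates
  ok <- logical(20)
  for (seed in seq_len(20)) {
    cfg <- sim_config(n_genes = 1, maternal_copies_per_gene = 2,
                      paternal_copies_per_gene = 0, recombinant_fraction = 0,
                      pseudogene_fraction = 0, seed = seed)
    panel <- simulate_parent_panel(cfg, seed)
    lib <- simulate_clone_library(panel, cfg, hoxclone:::derive_seed(seed, 2L),
                                  taxon = "T")
    types <- collapse_clones(lib$records, min_support = 2, merge_radius = 3)
    main <- types[types$support >= 2, ]
    ok[seed] <- nrow(main) == 2 && setequal(main$consensus,
                                            panel$haplotypes$sequence)
  }
  expect_gte(mean(ok), 0.95)
})
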
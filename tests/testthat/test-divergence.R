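test_that("identity is 100 for self and follows hand arithmetic", {
  x <- hoxclone:::random_dna(200)
  expect_equal(pairwise_identity(x, x, "nt"), 100)
  # 10-mer with exactly one mismatch, no gaps -> 90.0
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTACGTAA", "nt"), 90)
  # 1 mismatch in 11 columns -> 90.909... -> printed 90.9
  expect_equal(pairwise_identity("ACGTACGTACG", "ACGTACGTACT", "nt"), 90.9)
  # rounding is half away from zero to one decimal
  expect_equal(hoxclone:::round_half_up(94.45, 1), 94.5)
  expect_equal(hoxclone:::round_half_up(94.44, 1), 94.4)
  expect_error(pairwise_identity("", "ACGT", "nt"),
               class = "hoxclone_input_error")
})

test_that("identity is symmetric and gap columns leave the denominator", {
  set.seed(31)
  for (k in 1:10) {
    a <- hoxclone:::random_dna(300)
    ch <- strsplit(a, "")[[1]]
    at <- sample(300, 12)
    for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    b <- paste(ch[-(101:103)], collapse = "")  # plus a 3 bp deletion
    expect_equal(pairwise_identity(a, b, "nt"), pairwise_identity(b, a, "nt"))
  }
  # a pure deletion changes nothing when gaps are excluded ...
  a <- hoxclone:::random_dna(300)
  b <- paste0(substr(a, 1, 150), substr(a, 156, 300))
  expect_equal(pairwise_identity(a, b, "nt"), 100)
  # ... but lowers identity under the include-gaps variant
  expect_lt(pairwise_identity(a, b, "nt", include_gaps = TRUE), 100)
})

test_that("amino-acid identity propagates the pseudogene marker", {
  cds_a <- hoxclone:::random_cds(100)
  cds_b <- cds_a
  substr(cds_b, 10, 12) <- "TAA"   # premature stop
  pg_b <- call_pseudogene(cds_b)
  expect_true(pg_b$is_pseudogene)
  expect_identical(pairwise_identity(cds_a, cds_b, "aa", pseudo_b = pg_b), "P")
  expect_identical(pairwise_identity(cds_b, cds_a, "aa", pseudo_a = pg_b), "P")
  # without the flag a numeric identity is computed
  expect_true(is.numeric(pairwise_identity(cds_a, cds_a, "aa")))
  expect_equal(pairwise_identity(cds_a, cds_a, "aa"), 100)
})

test_that("identity matrices are symmetric with the P and dash conventions", {
  set.seed(32)
  cds <- setNames(vapply(1:4, function(i) hoxclone:::random_cds(80), ""),
                  c("T1 i", "T1 ii", "T2 i", "BSB"))
  # make pairs related rather than random
  cds[2] <- cds[1]; substr(cds[2], 5, 5) <- "A"
  pg <- c(`T1 i` = FALSE, `T1 ii` = TRUE, `T2 i` = FALSE, BSB = FALSE)
  im <- identity_matrix(cds, pg)
  expect_true(isSymmetric(im$nt))
  expect_true(all(diag(im$nt) == 100))
  expect_identical(im$aa["T1 i", "T1 ii"], "P")
  expect_identical(im$aa["T1 ii", "T2 i"], "P")
  expect_identical(diag(im$aa), c("100.0", "P", "100.0", "100.0"),
                   ignore_attr = TRUE)
  expect_match(im$cells["T1 i", "T1 ii"], "^[0-9.]+/P$")
  # identical pair prints 100.0/100.0
  cds2 <- setNames(c(cds[1], cds[1]), c("a", "b"))
  im2 <- identity_matrix(cds2)
  expect_identical(im2$cells["a", "b"], "100.0/100.0")
  expect_error(identity_matrix(cds[1]), class = "hoxclone_input_error")
})

test_that("neighbour joining reproduces additive distances and topology", {
  # hand-built additive matrix from tree ((A,B),(C,D)) with internal edge 3
  # and tip edges A=2, B=4, C=1, D=5
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 2 + 4
  d["A", "C"] <- d["C", "A"] <- 2 + 3 + 1
  d["A", "D"] <- d["D", "A"] <- 2 + 3 + 5
  d["B", "C"] <- d["C", "B"] <- 4 + 3 + 1
  d["B", "D"] <- d["D", "B"] <- 4 + 3 + 5
  d["C", "D"] <- d["D", "C"] <- 1 + 3 + 5
  tree <- ape::nj(as.dist(d))
  # additive input: patristic distances reproduce the matrix exactly
  got <- cophenetic(tree)[rownames(d), colnames(d)]
  expect_equal(got, d, tolerance = 1e-12)
  # and the generating split {A,B} | {C,D} is an edge of the tree
  parts <- ape::prop.part(tree)
  sets <- lapply(parts, function(p) sort(tree$tip.label[p]))
  expect_true(any(vapply(sets, identical, logical(1), y = c("A", "B"))) ||
                any(vapply(sets, identical, logical(1), y = c("C", "D"))))
})

test_that("perfectly separated gene groups are all recovered as clades", {
  set.seed(33)
  protein <- function(n) paste(sample(setdiff(strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]], ""), n, replace = TRUE), collapse = "")
  groups <- c("g1", "g2", "g3")
  aa <- character(0); tags <- character(0)
  for (g in groups) {
    base <- protein(120)
    for (i in 1:3) {   # identical members within a group
      aa <- c(aa, base); tags <- c(tags, g)
    }
  }
  names(aa) <- paste0(tags, "_", seq_along(aa))
  res <- clade_partition_check(aa, tags)
  expect_equal(res$n_groups_recovered, 3L)
  expect_true(all(res$per_gene))
  expect_error(clade_partition_check(aa[1:2], tags[1:2]),
               class = "hoxclone_input_error")
})

test_that("synthetic panels give one recovered clade per gene with anchors", {
  cfg <- sim_config(n_genes = 4, error_rate = 0, recombinant_fraction = 0,
                    seed = 44)
  panel <- simulate_parent_panel(cfg, 44)
  lib <- simulate_clone_library(panel, cfg, 44)
  res <- analyze_library(lib$records, panel, anchors = panel$anchors,
                         log_level = "quiet")
  expect_equal(res$clade$n_groups_recovered, 4L)
  expect_true(res$clade$anchor_ok)
  expect_s3_class(res$clade$tree, "phylo")
})
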
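# Structure annotation: coordinates are 1-based inclusive; exon1 may follow
# an untranslated leader; the intron must start GT and end AG.

# build an amplicon with an exactly planted structure
planted_amplicon <- function(exon1 = c(89L, 500L), intron = c(501L, 970L),
                             exon2 = c(971L, 1177L), seed = 1) {
  set.seed(seed)
  total <- exon2[2]
  leader <- hoxclone:::random_dna(exon1[1] - 1L)
  n_cod <- (exon1[2] - exon1[1] + 1L + exon2[2] - exon2[1] + 1L) %/% 3L
  cds <- hoxclone:::random_cds(n_cod)
  e1_len <- exon1[2] - exon1[1] + 1L
  intron_seq <- paste0("GT", hoxclone:::random_dna(intron[2] - intron[1] - 3L), "AG")
  seqs <- paste0(leader, substr(cds, 1, e1_len), intron_seq,
                 substr(cds, e1_len + 1L, nchar(cds)))
  pad <- total - nchar(seqs)   # CDS truncation to hit exact coordinates
  if (pad != 0L) seqs <- paste0(seqs, hoxclone:::random_dna(pad))
  list(sequence = substr(seqs, 1, total),
       structure = gene_structure(exon1, intron, exon2, total))
}

test_that("gene_structure enforces interval adjacency", {
  s <- gene_structure(c(89, 500), c(501, 970), c(971, 1177), 1177)
  expect_true(s$annotatable)
  expect_error(gene_structure(c(89, 500), c(502, 970), c(971, 1177), 1177),
               class = "hoxclone_input_error")
  expect_error(gene_structure(c(89, 500), c(501, 970), c(971, 1170), 1177),
               class = "hoxclone_input_error")
  expect_error(gene_structure(c(0, 500), c(501, 970), c(971, 1177), 1177),
               class = "hoxclone_input_error")
  u <- gene_structure(NULL, NULL, NULL, 1510, annotatable = FALSE)
  expect_false(u$annotatable)
  expect_null(u$exon1)
})

test_that("annotating a reference against itself returns its own structure", {
  amp <- planted_amplicon()
  got <- annotate_structure(amp$sequence, amp$sequence, amp$structure)
  expect_identical(got, amp$structure)
})

test_that("splice length matches the exon interval arithmetic", {
  # exon1 89-500 + exon2 971-1177 -> (500-89+1) + (1177-971+1) = 619
  amp <- planted_amplicon()
  cds <- splice_cds(amp$sequence, amp$structure)
  expect_equal(nchar(cds), 619L)
  # exon1 1-381 + exon2 683-879 -> 381 + 197 = 578
  amp2 <- planted_amplicon(exon1 = c(1L, 381L), intron = c(382L, 682L),
                           exon2 = c(683L, 879L), seed = 2)
  expect_equal(nchar(splice_cds(amp2$sequence, amp2$structure)), 578L)
  # splicing an unannotatable structure is unsupported
  u <- gene_structure(NULL, NULL, NULL, 1177, annotatable = FALSE)
  expect_error(splice_cds(amp$sequence, u),
               class = "hoxclone_unsupported_error")
  expect_error(splice_cds(substr(amp$sequence, 1, 100), amp$structure),
               class = "hoxclone_input_error")
})

test_that("annotation transfers across diverged haplotypes with intron indels", {
  amp <- planted_amplicon(seed = 3)
  # a sibling haplotype: 2% substitutions away plus a 5 bp intron deletion
  set.seed(4)
  chars <- strsplit(amp$sequence, "")[[1]]
  sub_at <- sample(setdiff(seq_along(chars), 499:505), 20)
  for (p in sub_at) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  sib <- paste(c(chars[1:600], chars[606:length(chars)]), collapse = "")
  got <- annotate_structure(sib, amp$sequence, amp$structure)
  expect_true(got$annotatable)
  expect_equal(got$exon1, c(89L, 500L))
  expect_equal(got$intron, c(501L, 965L))   # 5 bp shorter intron
  expect_equal(got$exon2, c(966L, 1172L))
  expect_equal(nchar(splice_cds(sib, got)), 619L)
})

test_that("zero-noise annotation recovers every planted intron boundary", {
  for (seed in 1:3) {
    cfg <- sim_config(n_genes = 2, error_rate = 0, seed = seed)
    panel <- simulate_parent_panel(cfg, seed)
    for (g in panel$genes$gene) {
      h <- panel$haplotypes[panel$haplotypes$gene == g, ]
      st <- panel$structures[panel$structures$gene == g, ]
      ref_i <- 1L   # annotate every haplotype from the first maternal copy
      ref_structure <- hoxclone:::structure_from_row(st[ref_i, ])
      for (i in seq_len(nrow(h))) {
        got <- annotate_structure(h$sequence[i], h$sequence[ref_i],
                                  ref_structure)
        expect_true(got$annotatable)
        expect_equal(got$intron[1], st$intron_start[i])
        expect_equal(got$intron[2], st$intron_end[i])
        expect_equal(got$exon1[1], st$exon1_start[i])
      }
    }
  }
})

test_that("annotation fails soft when no GT..AG placement exists", {
  amp <- planted_amplicon(seed = 5)
  # destroy the splice donor and every GT within the adjustment window
  chars <- strsplit(amp$sequence, "")[[1]]
  chars[494:509] <- "A"
  broken <- paste(chars, collapse = "")
  got <- annotate_structure(broken, amp$sequence, amp$structure)
  expect_false(got$annotatable)
  expect_equal(got$total_length, 1177L)
})
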
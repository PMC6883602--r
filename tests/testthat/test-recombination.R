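test_that("informative sites match an exhaustive per-column scan", {
  # no variation -> empty set, with a warning only for a singleton panel
  two <- rbind(a = s2c <- strsplit("ACGT", "")[[1]], b = strsplit("ACGT", "")[[1]])
  expect_length(find_informative_sites(two)$columns, 0L)
  expect_warning(one <- find_informative_sites(two[1, , drop = FALSE]),
                 "fewer than two")
  expect_length(one$columns, 0L)
  # single difference
  pair <- rbind(a = strsplit("ACGT", "")[[1]], b = strsplit("ACCT", "")[[1]])
  expect_equal(find_informative_sites(pair)$columns, 3L)
  # random panels against the brute-force column scan
  set.seed(11)
  for (k in 1:25) {
    mat <- matrix(sample(c("A", "C", "G", "T", "-"), 3 * 60, replace = TRUE,
                         prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), nrow = 3)
    rownames(mat) <- c("a", "b", "c")
    expect_equal(find_informative_sites(mat)$columns, scan_informative(mat))
  }
})

test_that("the DP equals brute-force enumeration over all donor paths", {
  set.seed(21)
  for (k in 1:60) {
    n_hap <- sample(2:4, 1)
    m_target <- switch(n_hap - 1, 12, 9, 7)  # cap the path count
    inst <- random_dp_instance(n_hap, m_target + 6)
    lambda <- sample(c(0, 0.5, 1, 2, 3), 1)
    cost <- instance_cost(inst)
    if (ncol(cost) < 2 || ncol(cost) > m_target) next
    got <- dp_score(inst, lambda)
    expect_equal(got$penalized_score, brute_force_score(cost, lambda))
  }
})

test_that("an infinite switch penalty reduces to nearest-haplotype", {
  set.seed(22)
  for (k in 1:15) {
    inst <- random_dp_instance(3, 14)
    cost <- instance_cost(inst)
    m <- ncol(cost)
    if (m == 0) next
    got <- dp_score(inst, lambda = m + 1)   # lambda >= #informative sites
    expect_length(got$segments, 1L)
    expect_equal(got$switches, 0L)
    expect_equal(got$penalized_score, min(rowSums(cost)))
  }
})

test_that("at lambda 0 the score is the column-wise minimum", {
  set.seed(23)
  for (k in 1:15) {
    inst <- random_dp_instance(3, 12)
    cost <- instance_cost(inst)
    if (ncol(cost) == 0) next
    got <- dp_score(inst, lambda = 0, min_diag = 1)
    expect_equal(got$penalized_score, sum(apply(cost, 2, min)))
  }
})

test_that("pure parental queries yield a single segment with no mismatch", {
  mat <- toy_panel()
  seqs <- apply(mat, 1, paste, collapse = "")
  comp <- segment_query(seqs[["B"]], mat)
  expect_identical(comp$segments, "B")
  expect_equal(comp$mismatches, 0)
  expect_equal(nrow(comp$breakpoints), 0L)
})

test_that("planted two-part mosaics are segmented with contained junctions", {
  # 40% of A then 60% of B, junction inside the reported interval
  set.seed(24)
  world <- small_sim(24, n_genes = 1, error_rate = 0, indel_rate = 0)
  msa <- world$panel$alignments[[1]]
  labs <- rownames(msa)
  cut <- round(ncol(msa) * 0.4)
  query <- paste(c(msa[1, 1:cut], msa[2, (cut + 1):ncol(msa)]), collapse = "")
  comp <- segment_query(query, msa)
  expect_identical(comp$segments, labs[1:2])
  expect_equal(nrow(comp$breakpoints), 1L)
  expect_lte(comp$breakpoints$after_site, cut)
  expect_gt(comp$breakpoints$before_site, cut)
  expect_equal(comp$mismatches, 0)
})

test_that("maternal-paternal-maternal mosaics give an X, Y-BSB, X composition", {
  world <- small_sim(25, n_genes = 1, error_rate = 0, indel_rate = 0)
  msa <- world$panel$alignments[[1]]
  n <- ncol(msa)
  i <- grep("i$", rownames(msa), value = TRUE)[1]
  bsb <- grep("-BSB$", rownames(msa), value = TRUE)
  third <- round(n / 3)
  query <- paste(c(msa[i, 1:third], msa[bsb, (third + 1):(2 * third)],
                   msa[i, (2 * third + 1):n]), collapse = "")
  comp <- segment_query(query, msa)
  expect_identical(comp$segments, c(i, bsb, i))
  expect_equal(comp$switches, 2L)
})

test_that("relabelling the panel permutes the output labels identically", {
  world <- small_sim(26, n_genes = 1, error_rate = 0, indel_rate = 0)
  msa <- world$panel$alignments[[1]]
  cut <- round(ncol(msa) * 0.5)
  query <- paste(c(msa[1, 1:cut], msa[3, (cut + 1):ncol(msa)]), collapse = "")
  comp1 <- segment_query(query, msa)
  perm <- msa[c(3, 1, 2), ]
  comp2 <- segment_query(query, perm)
  expect_identical(comp1$segments, comp2$segments)
  expect_equal(comp1$penalized_score, comp2$penalized_score)
  expect_equal(comp1$breakpoints, comp2$breakpoints)
})

test_that("the min_diag filter suppresses single-site switches", {
  # a single donor-supported mismatch must not produce a breakpoint
  mat <- rbind(A = rep("A", 20), B = rep(c("A", "C"), 10))
  mat["B", c(1, 3)] <- c("G", "G")
  query <- mat["A", ]
  query[10] <- mat["B", 10]
  inst <- list(mat = mat, query = query)
  got <- dp_score(inst, lambda = 0.5, min_diag = 2)
  expect_identical(got$segments, "A")
})

test_that("classification separates putative, recombinant and novel", {
  world <- small_sim(27, n_genes = 1, error_rate = 0, indel_rate = 0)
  msa <- world$panel$alignments[[1]]
  seqs <- setNames(apply(msa, 1, function(r) paste(r[r != "-"], collapse = "")),
                   rownames(msa))
  # a parental haplotype is putative
  expect_identical(classify_clone(seqs[[1]], msa)$class, "putative")
  # a planted half-half mosaic is recombinant with the right donors
  cut <- round(ncol(msa) / 2)
  mosaic <- paste(c(msa[1, 1:cut], msa[3, (cut + 1):ncol(msa)]), collapse = "")
  got <- classify_clone(mosaic, msa)
  expect_identical(got$class, "recombinant")
  expect_identical(got$composition$segments, rownames(msa)[c(1, 3)])
  # a heavily diverged sequence is novel
  set.seed(1)
  ch <- strsplit(seqs[[1]], "")[[1]]
  at <- sample(length(ch), round(length(ch) * 0.2))
  for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  novel <- paste(ch, collapse = "")
  got2 <- classify_clone(novel, msa, identity_floor = 90)
  expect_identical(got2$class, "novel")
  expect_lt(got2$best_identity, 90)
  expect_null(got2$composition)
  expect_error(classify_clone("ACGT", msa[0, , drop = FALSE]),
               class = "hoxclone_input_error")
})

test_that("breakpoint intervals contain the true junction on clean data", {
  for (seed in 1:5) {
    world <- small_sim(seed + 40, n_genes = 1, error_rate = 0,
                       recombinant_fraction = 0.4)
    msa <- world$panel$alignments[[1]]
    tr <- world$lib$truth
    rec <- tr[tr$n_segments > 1, ]
    for (i in seq_len(nrow(rec))) {
      query <- world$lib$records$sequence[world$lib$records$clone_id ==
                                            rec$clone_id[i]]
      comp <- segment_query(query, msa)
      expect_identical(paste(comp$segments, collapse = " + "), rec$origin[i])
      bps <- as.integer(strsplit(rec$breakpoints[i], ",")[[1]])
      expect_equal(nrow(comp$breakpoints), length(bps))
      expect_true(all(comp$breakpoints$after_site <= bps &
                        bps < comp$breakpoints$before_site))
    }
  }
})
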
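# Shared fixtures and independent oracles, built in code at test time.

# A tiny hand-built donor panel in common coordinates (no gaps): three
# haplotypes over 24 columns. Columns where members differ are known by
# construction.
toy_panel <- function() {
  m <- rbind(
    A = s2c("ACGTACGTACGTACGTACGTACGT"),
    B = s2c("ACGTACGAACGTACCTACGTACCT"),
    C = s2c("ATGTACGTACATACGTACGAACGT"))
  m
}

# independent per-column scan for informative sites (the brute-force oracle
# for find_informative_sites)
scan_informative <- function(mat) {
  which(vapply(seq_len(ncol(mat)), function(j) {
    b <- mat[, j][mat[, j] != "-"]
    length(unique(b)) >= 2L
  }, logical(1)))
}

# Exhaustive enumeration of all donor-label paths over m informative sites:
# the independent oracle for the DP. cost[h, j] = mismatch cost of donor h at
# site j. Returns the minimal penalised score.
brute_force_score <- function(cost, lambda) {
  H <- nrow(cost); m <- ncol(cost)
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), m)))
  site_cost <- matrix(0, nrow(paths), m)
  for (j in seq_len(m)) site_cost[, j] <- cost[cbind(paths[, j], j)]
  switches <- if (m > 1L) {
    rowSums(paths[, -1L, drop = FALSE] != paths[, -m, drop = FALSE])
  } else 0
  min(rowSums(site_cost) + lambda * switches)
}

# random DP instance: an ungapped panel matrix plus a query laid over the
# same columns (mosaic of panel rows with sprinkled mutations)
random_dp_instance <- function(n_hap, m) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n_hap * m, replace = TRUE),
                nrow = n_hap)
  rownames(mat) <- paste0("h", seq_len(n_hap))
  path <- numeric(m)
  path[1] <- sample(n_hap, 1)
  for (j in seq_len(m - 1)) {
    path[j + 1] <- if (runif(1) < 0.3) sample(n_hap, 1) else path[j]
  }
  query <- mat[cbind(path, seq_len(m))]
  mut <- runif(m) < 0.15
  query[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
  list(mat = mat, query = query)
}

# run the package DP on an instance without any alignment step
dp_score <- function(inst, lambda, min_diag = 1L) {
  panel <- hoxclone:::as_hap_panel(inst$mat)
  proj <- list(chars = inst$query, query_pos = seq_along(inst$query))
  hoxclone:::segment_projected(proj, panel, lambda = lambda,
                               min_diag = min_diag)
}

# cost matrix of an ungapped instance, restricted to informative columns
instance_cost <- function(inst) {
  cols <- scan_informative(inst$mat)
  cost <- matrix(0, nrow(inst$mat), length(cols))
  for (h in seq_len(nrow(inst$mat))) {
    cost[h, ] <- as.numeric(inst$mat[h, cols] != inst$query[cols])
  }
  cost
}

# small simulated world shared by several tests
small_sim <- function(seed, n_genes = 2L, ...) {
  cfg <- sim_config(n_genes = n_genes, seed = seed, ...)
  panel <- simulate_parent_panel(cfg, seed)
  lib <- simulate_clone_library(panel, cfg, hoxclone:::derive_seed(seed, 1000L, 1L),
                                taxon = "SYN-F1")
  list(cfg = cfg, panel = panel, lib = lib)
}

# per-clone detected calls of an analysis (label for putative/novel types,
# composition string for recombinant types), keyed by clone id
per_clone_calls <- function(types) {
  out <- list()
  for (i in seq_len(nrow(types))) {
    ids <- strsplit(types$members[i], ";", fixed = TRUE)[[1]]
    call <- if (types$class[i] == "recombinant") types$composition[i] else types$label[i]
    out[[length(out) + 1L]] <- data.frame(clone_id = ids, call = call,
                                          type_row = i,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
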
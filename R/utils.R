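# Internal helpers. All coordinates in this package are 1-based inclusive,
# matching the convention of the exon1/intron/exon2 report tables.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
IUPAC_LETTERS <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                   "V", "H", "D", "B", "N")
ALL_CODONS <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                              DNA_BASES, paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

`%||%` <- function(a, b) if (is.null(a)) b else a

s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
c2s <- function(x) paste(x, collapse = "")

random_dna <- function(n) c2s(sample(DNA_BASES, n, replace = TRUE))

# random coding sequence with no internal stop codon, length 3 * n_codons
random_cds <- function(n_codons) c2s(sample(SENSE_CODONS, n_codons, replace = TRUE))

# round half away from zero (tables print e.g. 94.45 -> 94.5, base round() does not)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

roman_label <- function(k) tolower(as.character(utils::as.roman(k)))

# Stable integer stream derivation: one top-level seed, per-component streams
# hashed from (seed, indices...). Stays below 2^31 so set.seed() accepts it.
derive_seed <- function(seed, ...) {
  idx <- list(...)
  h <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (k in idx) {
    if (is.character(k)) k <- sum(utf8ToInt(k))
    h <- (h * 48271 + (as.double(k) + 1) * 9349) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# draw one element; immune to sample()'s scalar expansion
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# Alignment columns this close to a gap column carry no reliable evidence:
# gap placement around indels is alignment-ambiguous, and independently
# aligned rows can be mutually shifted within such windows.
GAP_BUFFER <- 12L

gap_adjacent_columns <- function(gap_logical, buffer = GAP_BUFFER) {
  n <- length(gap_logical)
  out <- rep(FALSE, n)
  for (g in which(gap_logical)) {
    out[max(1L, g - buffer):min(n, g + buffer)] <- TRUE
  }
  out
}

config_error <- function(field, msg) {
  stop(structure(
    class = c("hoxclone_config_error", "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", field, msg), call = NULL)
  ))
}

input_error <- function(msg, ...) {
  stop(structure(
    class = c("hoxclone_input_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

unsupported_error <- function(msg, ...) {
  stop(structure(
    class = c("hoxclone_unsupported_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

is_iupac_dna <- function(x) {
  grepl(sprintf("^[%s]+$", paste(IUPAC_LETTERS, collapse = "")),
        toupper(x))
}

translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"   # codons containing IUPAC ambiguity letters
  aa
}

split_codons <- function(cds, frame_offset = 0L) {
  chars <- s2c(toupper(cds))
  usable <- length(chars) - frame_offset
  n_cod <- usable %/% 3L
  if (n_cod < 1L) return(character(0))
  idx <- frame_offset + seq_len(n_cod * 3L)
  m <- matrix(chars[idx], nrow = 3L)
  apply(m, 2L, paste, collapse = "")
}

# ---- pairwise global alignment (Biostrings) --------------------------------

default_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = 5, gap_ext = 1)
}

nt_submat <- function(scoring = default_scoring()) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
}

aa_submat <- function(scoring = default_scoring()) {
  letters <- c(Biostrings::AA_STANDARD, "B", "J", "Z", "X", "U", "O", "*")
  m <- matrix(scoring$mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m
}

# Global alignment of two sequences; returns the two gapped strings as
# character vectors of equal length.
align_pair <- function(a, b, type = c("nt", "aa"), scoring = default_scoring()) {
  type <- match.arg(type)
  if (nchar(a) == 0L || nchar(b) == 0L) input_error("cannot align empty sequence")
  if (type == "nt") {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
      type = "global", substitutionMatrix = nt_submat(scoring),
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = aa_submat(scoring),
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
  }
  list(a = s2c(as.character(Biostrings::alignedPattern(pa))),
       b = s2c(as.character(Biostrings::alignedSubject(pa))))
}
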
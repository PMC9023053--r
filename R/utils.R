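# Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded package functions never perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Strip the allele suffix from a V/J gene label
#'
#' Repertoire callers disagree on allele-level annotation, so gene labels
#' are compared after dropping everything from the first `*` on
#' (`"TRBV20-1*01"` becomes `"TRBV20-1"`).
#'
#' @param x character vector of gene labels.
#' @return character vector without allele suffixes.
#' @export
strip_allele <- function(x) sub("\\*.*$", "", x)

# Canonical clonotype key: amino-acid CDR3 plus allele-stripped V and J.
clonotype_key <- function(cdr3aa, v, j) {
  paste(cdr3aa, strip_allele(v), strip_allele(j), sep = "|")
}

#' Translate in-frame CDR3 nucleotide sequences
#'
#' Vectorized translation using the standard genetic code
#' (`Biostrings::GENETIC_CODE`); stop codons appear as `"*"`.
#' All inputs must have length divisible by 3 and contain only ACGT.
#' @noRd
translate_nt <- function(nt) {
  out <- character(length(nt))
  if (!length(nt)) return(out)
  len <- nchar(nt)
  if (any(len %% 3L != 0L)) stop("nucleotide length not divisible by 3")
  gc_tab <- Biostrings::GENETIC_CODE
  for (L in unique(len)) {
    idx <- which(len == L)
    if (L == 0L) { out[idx] <- ""; next }
    s <- nt[idx]
    aa <- vector("list", L / 3L)
    for (k in seq_len(L / 3L)) {
      codon <- substr(s, 3L * k - 2L, 3L * k)
      aa[[k]] <- unname(gc_tab[codon])
    }
    out[idx] <- do.call(paste0, lapply(aa, unname))
  }
  out
}

# Pairwise Hamming distance of two equal-length strings.
hamming1_pair <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Number of mismatches of each element of `seqs` against `center`
# (all the same length as center; caller filters lengths first).
mismatch_count <- function(seqs, center) {
  L <- nchar(center)
  n <- length(seqs)
  if (!n) return(integer(0))
  mm <- integer(n)
  for (p in seq_len(L)) {
    mm <- mm + (substr(seqs, p, p) != substr(center, p, p))
  }
  mm
}

# Masked variants of each sequence: for every position, the string with
# that position replaced by ".". Returns a data.table(idx, pos, masked).
masked_table <- function(seqs) {
  L <- nchar(seqs[1L])
  n <- length(seqs)
  idx <- rep(seq_len(n), L)
  pos <- rep(seq_len(L), each = n)
  masked <- character(n * L)
  for (p in seq_len(L)) {
    masked[((p - 1L) * n + 1L):(p * n)] <-
      paste0(substr(seqs, 1L, p - 1L), ".", substr(seqs, p + 1L, L))
  }
  data.table::data.table(idx = idx, pos = pos, masked = masked)
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
}

check_prob_vector <- function(p, what, tol = 1e-12) {
  if (any(p < 0)) stop(what, " contains negative probabilities")
  if (abs(sum(p) - 1) > tol) stop(what, " must sum to 1 (got ", sum(p), ")")
  invisible(p)
}
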
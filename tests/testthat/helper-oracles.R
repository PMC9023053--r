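# Fixtures and independent brute-force oracles used across the suite.
# Oracles deliberately avoid the package's hash-bucket / step-up /
# conditional-NB code paths.

# Simulation pools are expensive; one cache is shared across test files
# (keys include model identity via the derived per-class seed).
shared_alice_cache <- new.env(parent = emptyenv())

# Toy recombination model with exact hand-enumerable structure:
# V contributes CAS (9 nt), J contributes FF (6 nt), inserts of 0-3 nt
# from {A, G}. Productive outcomes: CASFF (p .5 | productive) and
# CAS[K/R/E/G]FF (p .125 each | productive); 1- and 2-nt inserts are
# out-of-frame rejections (total rejection mass 0.2).
exact_toy_model <- function() {
  recombination_model(
    v_segments = c("TRBV-T" = "TGTGCCAGC"),
    j_segments = c("TRBJ-T" = "TTTTTC"),
    v_deletion_dist = 1, j_deletion_dist = 1,
    insertion_length_dist = c(0.4, 0.1, 0.1, 0.4),
    insertion_base_probs = c(A = 0.5, C = 0, G = 0.5, T = 0),
    vj_usage = data.frame(v = "TRBV-T", j = "TRBJ-T", prob = 1))
}

# Fully deterministic single-sequence model: always emits CASFF.
degenerate_model <- function() {
  recombination_model(
    v_segments = c("V1" = "TGTGCCAGC"),
    j_segments = c("J1" = "TTTTTC"),
    v_deletion_dist = 1, j_deletion_dist = 1,
    insertion_length_dist = 1,
    insertion_base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    vj_usage = data.frame(v = "V1", j = "J1", prob = 1))
}

# Independent enumeration of the exact_toy_model ball probability
# (conditional on productivity), written from the event table above.
toy_ball_oracle <- function(query) {
  outcomes <- data.frame(
    aa = c("CASFF", "CASKFF", "CASRFF", "CASEFF", "CASGFF"),
    p = c(0.5, 0.125, 0.125, 0.125, 0.125))
  sel <- nchar(outcomes$aa) == nchar(query)
  in_ball <- vapply(outcomes$aa[sel], function(a)
    sum(strsplit(a, "")[[1]] != strsplit(query, "")[[1]]) <= 1, NA)
  sum(outcomes$p[sel][in_ball])
}

# Small random repertoire with a collision-prone alphabet so that
# Hamming-1 neighbors actually occur.
random_fixture <- function(n, seed, alphabet = c("A", "S", "T", "G"),
                           lens = 4:7, vs = c("TRBV1", "TRBV2"),
                           js = c("TRBJ1", "TRBJ2")) {
  set.seed(seed)
  cdr3 <- vapply(sample(lens, n, replace = TRUE), function(L)
    paste(c("C", sample(alphabet, L - 2L, replace = TRUE), "F"),
          collapse = ""), "")
  dt <- data.table::data.table(
    cdr3aa = cdr3, v = sample(vs, n, replace = TRUE),
    j = sample(js, n, replace = TRUE))
  dt <- unique(dt, by = c("cdr3aa", "v", "j"))
  dt[, count := sample(2:50, .N, replace = TRUE)]
  dt[, freq := count / sum(count)]
  dt
}

# O(n^2) all-pairs neighbor oracle under the TEST rule (same V, J,
# length; Hamming <= 1). Character-matrix arithmetic, no hashing.
oracle_neighbor_counts <- function(dt) {
  n <- nrow(dt)
  d <- integer(n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      if (dt$v[i] != dt$v[k] || dt$j[i] != dt$j[k]) next
      if (nchar(dt$cdr3aa[i]) != nchar(dt$cdr3aa[k])) next
      mm <- sum(strsplit(dt$cdr3aa[i], "")[[1]] !=
                  strsplit(dt$cdr3aa[k], "")[[1]])
      if (mm <= 1L) { d[i] <- d[i] + 1L; d[k] <- d[k] + 1L }
    }
  }
  d
}

# O(n^2) all-pairs edge oracle under the GRAPH rule (length equal,
# Hamming <= 1, V/J ignored). Returns a sorted two-column matrix.
oracle_edges <- function(cdr3) {
  n <- length(cdr3)
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (k in (i + 1L):n) {
        if (nchar(cdr3[i]) != nchar(cdr3[k])) next
        mm <- sum(strsplit(cdr3[i], "")[[1]] !=
                    strsplit(cdr3[k], "")[[1]])
        if (mm <= 1L) out[[length(out) + 1L]] <- c(i, k)
      }
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

# Textbook Benjamini-Hochberg step-up, implemented as the direct
# definition: q_i = min over j >= rank(i) of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (r in seq_len(m)) {
    cand <- vapply(r:m, function(jj) m * p[o[jj]] / jj, 0)
    q[o[r]] <- min(1, min(cand))
  }
  q
}

# Doubled-smaller-tail two-sided binomial oracle for the conditional
# Poisson-limit test: SA | SA + SB = t ~ Binomial(t, na / (na + nb)).
oracle_binomial_two_sided <- function(sa, t, na, nb) {
  if (t == 0) return(1)
  pr <- na / (na + nb)
  lo <- stats::pbinom(sa, t, pr)
  hi <- 1 - stats::pbinom(sa - 1, t, pr)
  min(1, 2 * min(lo, hi))
}

# Brute-force specificity matcher: re-states the three rules without
# any of the package's candidate filtering.
oracle_match <- function(q_cdr3, db, central_lo = 4L, central_hi = 3L,
                         patient_hla = NULL) {
  hits <- integer(0)
  L <- nchar(q_cdr3)
  qc <- strsplit(q_cdr3, "")[[1]]
  for (r in seq_len(nrow(db))) {
    if (nchar(db$cdr3aa[r]) != L) next
    rc <- strsplit(db$cdr3aa[r], "")[[1]]
    dif <- which(qc != rc)
    ok <- FALSE
    if (length(dif) == 0L) ok <- TRUE
    if (length(dif) == 1L) {
      p <- dif[1L]
      if (p >= central_lo && p <= L - central_hi &&
          aa_group(qc[p]) == aa_group(rc[p])) ok <- TRUE
    }
    if (ok && !is.null(patient_hla)) {
      a <- db$hla[r]
      if (grepl(":", a, fixed = TRUE)) {
        ok <- sub("^([^:]*:[^:]*).*$", "\\1", a) %in%
          sub("^([^:]*:[^:]*).*$", "\\1", patient_hla)
      } else {
        ok <- a %in% sub(":.*$", "", patient_hla)
      }
    }
    if (ok) hits <- c(hits, r)
  }
  hits
}

# Two-sample toy matrix around a tested row (sa | sb): identical
# filler rows pin the normalization factors at 1 and a balance row
# equalizes the library sizes, so the conditional test sees the raw
# sums and the Poisson-limit law is exactly Binomial(t, 1/2).
binom_toy <- function(sa, sb, B = 40L) {
  m <- rbind(test = c(sa, sb),
             bal = c(B - sa, B - sb),
             matrix(10L, 5, 2, dimnames = list(paste0("f", 1:5), NULL)))
  colnames(m) <- c("s1", "s2")
  count_matrix(m, c("A", "B"))
}

# Tiny literal repertoire builder for worked examples.
mini_rep <- function(counts, cdr3aa, v = "TRBV1", j = "TRBJ1",
                     sample_id = "s") {
  n <- length(counts)
  repertoire(data.frame(count = counts, cdr3aa = cdr3aa,
                        v = rep_len(v, n), j = rep_len(j, n)),
             sample_id = sample_id)
}
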
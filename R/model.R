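# generative_model: V(D)J recombination model used as Monte-Carlo null,
# exact-enumeration oracle, and synthetic-repertoire generator.
#
# The model is D-less: CDR3 = trimmed V 3' contribution + N-insert +
# trimmed J 5' contribution. Deletion-length and insert-length
# distributions are shared across segments; insert bases are i.i.d.
# A rearrangement is productive when its length is divisible by 3, its
# translation is stop-free, and the amino-acid sequence starts with C
# and ends with F or W.

#' Construct a V(D)J recombination model
#'
#' @param v_segments named character vector: V gene -> 3' nucleotides
#'   contributed to the CDR3 (starting with the conserved C codon).
#' @param j_segments named character vector: J gene -> 5' nucleotides
#'   contributed to the CDR3 (ending with the conserved F/W codon).
#' @param v_deletion_dist,j_deletion_dist probability vectors over
#'   deletion lengths 0, 1, 2, ... applied to the V 3' / J 5' ends.
#' @param insertion_length_dist probability vector over N-insert
#'   lengths 0, 1, 2, ... (in nucleotides).
#' @param insertion_base_probs named probability vector over A, C, G, T.
#' @param vj_usage data.frame with columns `v`, `j`, `prob` giving the
#'   joint usage of (V, J) pairs; probabilities must sum to 1.
#' @return an object of class `recomb_model`.
#' @export
recombination_model <- function(v_segments, j_segments,
                                v_deletion_dist, j_deletion_dist,
                                insertion_length_dist,
                                insertion_base_probs, vj_usage) {
  v_segments <- unlist(v_segments); j_segments <- unlist(j_segments)
  check_prob_vector(v_deletion_dist, "v_deletion_dist")
  check_prob_vector(j_deletion_dist, "j_deletion_dist")
  check_prob_vector(insertion_length_dist, "insertion_length_dist")
  insertion_base_probs <- insertion_base_probs[c("A", "C", "G", "T")]
  if (anyNA(insertion_base_probs))
    stop("insertion_base_probs must name A, C, G, T")
  check_prob_vector(insertion_base_probs, "insertion_base_probs")
  usage <- data.table::as.data.table(vj_usage)
  if (!all(c("v", "j", "prob") %in% names(usage)))
    stop("vj_usage needs columns v, j, prob")
  usage <- usage[prob > 0]
  if (!nrow(usage)) stop("vj_usage support is empty")
  check_prob_vector(usage$prob, "vj_usage")
  if (!all(usage$v %in% names(v_segments)))
    stop("vj_usage references unknown V segment")
  if (!all(usage$j %in% names(j_segments)))
    stop("vj_usage references unknown J segment")
  if (length(v_deletion_dist) - 1L > min(nchar(v_segments)) ||
      length(j_deletion_dist) - 1L > min(nchar(j_segments)))
    stop("deletion distribution support exceeds a segment length")
  data.table::setorder(usage, v, j)
  structure(list(v_segments = v_segments, j_segments = j_segments,
                 v_deletion_dist = as.numeric(v_deletion_dist),
                 j_deletion_dist = as.numeric(j_deletion_dist),
                 insertion_length_dist = as.numeric(insertion_length_dist),
                 insertion_base_probs = insertion_base_probs,
                 vj_usage = usage),
            class = "recomb_model")
}

#' @export
print.recomb_model <- function(x, ...) {
  cat(sprintf(paste0("<recomb_model> %d V x %d J segments, %d (V,J) pairs",
                     " in use;\n  deletions 0-%d nt, inserts 0-%d nt\n"),
              length(x$v_segments), length(x$j_segments), nrow(x$vj_usage),
              length(x$v_deletion_dist) - 1L,
              length(x$insertion_length_dist) - 1L))
  invisible(x)
}

#' Read / write a recombination model specification file
#'
#' The on-disk format is JSON with the seven field groups of the model
#' (segments, deletion and insertion distributions, base composition,
#' VJ usage).
#'
#' @param path file path.
#' @return `read_model` returns a `recomb_model`; `write_model` returns
#'   `path` invisibly.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  sp <- jsonlite::read_json(path, simplifyVector = TRUE)
  recombination_model(
    v_segments = unlist(sp$v_segments),
    j_segments = unlist(sp$j_segments),
    v_deletion_dist = sp$v_deletion_dist,
    j_deletion_dist = sp$j_deletion_dist,
    insertion_length_dist = sp$insertion_length_dist,
    insertion_base_probs = unlist(sp$insertion_base_probs),
    vj_usage = data.table::as.data.table(sp$vj_usage))
}

#' @rdname read_model
#' @param model a `recomb_model`.
#' @export
write_model <- function(model, path) {
  out <- list(v_segments = as.list(model$v_segments),
              j_segments = as.list(model$j_segments),
              v_deletion_dist = model$v_deletion_dist,
              j_deletion_dist = model$j_deletion_dist,
              insertion_length_dist = model$insertion_length_dist,
              insertion_base_probs = as.list(model$insertion_base_probs),
              vj_usage = model$vj_usage)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Packaged example models
#'
#' `"toy"` is a two-gene model small enough for exact enumeration;
#' `"human"` is a human-like model with 48 V and 13 J labels, geometric
#' deletion lengths (mean ~4 nt) and 0-20 nt inserts.
#'
#' @param name `"toy"` or `"human"`.
#' @return a `recomb_model`.
#' @export
example_model <- function(name = c("toy", "human")) {
  name <- match.arg(name)
  read_model(system.file("extdata", paste0(name, "_model.json"),
                         package = "tcrconv", mustWork = TRUE))
}

#' Build the packaged human-like recombination model
#'
#' Deterministic construction (internal fixed seed) of a model with
#' `n_v` V and `n_j` J labels: every V 3' contribution starts with the
#' conserved TGT/TGC cysteine codon, every J 5' contribution ends with a
#' TTC/TTT phenylalanine or TGG tryptophan codon, deletion lengths are
#' truncated-geometric with mean about 4 nt, insert lengths span 0-20 nt,
#' and VJ usage is a non-uniform outer product of decaying gene weights.
#'
#' @param n_v,n_j number of V and J labels.
#' @param seed internal construction seed (fixed default so the packaged
#'   fixture is reproducible).
#' @return a `recomb_model`.
#' @export
build_human_model <- function(n_v = 48, n_j = 13, seed = 20260911) {
  with_seed(seed, {
    seg_len <- 18L
    # germline segment contributions are stop-free in their canonical
    # frame (V read from its start, J read back from its fixed 3' end);
    # junctional frame shifts still produce stops downstream.
    codons <- apply(expand.grid(c("T", "C", "A", "G"),
                                c("T", "C", "A", "G"),
                                c("T", "C", "A", "G")), 1L, paste,
                    collapse = "")
    codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
    rand_codons <- function(k) paste(sample(codons, k, replace = TRUE),
                                     collapse = "")
    v_names <- paste0("TRBV", seq_len(n_v))
    j_names <- paste0("TRBJ", rep(1:2, length.out = n_j), "-",
                      unlist(lapply(c(ceiling(n_j / 2), floor(n_j / 2)),
                                    seq_len)))
    v_segments <- vapply(v_names, function(nm)
      paste0(sample(c("TGT", "TGC"), 1L), "GCC",
             rand_codons(seg_len / 3L - 2L)),
      "", USE.NAMES = TRUE)
    j_segments <- vapply(j_names, function(nm)
      paste0(rand_codons(seg_len / 3L - 1L),
             sample(c("TTC", "TTT", "TGG"), 1L, prob = c(.55, .35, .10))),
      "", USE.NAMES = TRUE)
    # truncated geometric deletions, mean ~4 nt before truncation;
    # support capped so the conserved anchor codon always survives.
    del <- dgeom(0:12, prob = 0.15)
    del <- del / sum(del)
    ins <- dgeom(0:20, prob = 0.12)
    ins <- ins / sum(ins)
    v_w <- exp(rnorm(n_v, sd = 0.8)) * 0.85^seq_len(n_v)
    j_w <- exp(rnorm(n_j, sd = 0.5))
    usage <- data.table::CJ(v = v_names, j = j_names, sorted = TRUE)
    usage[, prob := v_w[match(v, v_names)] * j_w[match(j, j_names)]]
    usage[, prob := prob / sum(prob)]
    recombination_model(v_segments, j_segments, del, del, ins,
                        c(A = .24, C = .26, G = .30, T = .20), usage)
  })
}

# ---- sampling ---------------------------------------------------------

# Vectorized draw of n rearrangements conditional on a (v, j) pair.
# Returns data.table(cdr3nt, cdr3aa, productive).
simulate_vj_raw <- function(model, v_gene, j_gene, n) {
  vseq <- model$v_segments[[v_gene]]
  jseq <- model$j_segments[[j_gene]]
  if (is.null(vseq) || is.null(jseq))
    stop("(", v_gene, ", ", j_gene, ") not in model segment tables")
  vd <- sample.int(length(model$v_deletion_dist), n, replace = TRUE,
                   prob = model$v_deletion_dist) - 1L
  jd <- sample.int(length(model$j_deletion_dist), n, replace = TRUE,
                   prob = model$j_deletion_dist) - 1L
  il <- sample.int(length(model$insertion_length_dist), n, replace = TRUE,
                   prob = model$insertion_length_dist) - 1L
  inserts <- character(n)
  if (any(il > 0L)) {
    for (L in unique(il[il > 0L])) {
      idx <- which(il == L)
      mat <- matrix(sample(c("A", "C", "G", "T"), length(idx) * L,
                           replace = TRUE,
                           prob = model$insertion_base_probs),
                    ncol = L)
      inserts[idx] <- do.call(paste0, as.data.frame(mat))
    }
  }
  nt <- paste0(substr(rep(vseq, n), 1L, nchar(vseq) - vd), inserts,
               substring(rep(jseq, n), jd + 1L))
  len <- nchar(nt)
  aa <- rep(NA_character_, n)
  inframe <- len %% 3L == 0L & len > 0L
  if (any(inframe)) aa[inframe] <- translate_nt(nt[inframe])
  productive <- inframe & !is.na(aa) & !grepl("*", aa, fixed = TRUE) &
    startsWith(aa, "C") & (endsWith(aa, "F") | endsWith(aa, "W"))
  data.table::data.table(cdr3nt = nt, cdr3aa = aa, productive = productive)
}

#' Sample a single V(D)J rearrangement
#'
#' Draws a (V, J) pair from the usage distribution, deletion lengths,
#' an insert length and insert bases, concatenates trimmed V + insert +
#' trimmed J, and applies the productivity filter (in-frame, stop-free,
#' C...F/W anchors). Non-productive draws are *rejected*: the function
#' returns `NULL` rather than resampling, so callers can measure the
#' rejection rate.
#'
#' @param model a `recomb_model`.
#' @param rng_seed optional integer seed.
#' @return `NULL` (rejection) or a list with `v_gene`, `j_gene`,
#'   `cdr3_nt`, `cdr3_aa`.
#' @export
sample_rearrangement <- function(model, rng_seed = NULL) {
  with_seed(rng_seed, {
    k <- sample.int(nrow(model$vj_usage), 1L, prob = model$vj_usage$prob)
    draw <- simulate_vj_raw(model, model$vj_usage$v[k],
                            model$vj_usage$j[k], 1L)
    if (!draw$productive[1L]) return(NULL)
    list(v_gene = model$vj_usage$v[k], j_gene = model$vj_usage$j[k],
         cdr3_nt = draw$cdr3nt[1L], cdr3_aa = draw$cdr3aa[1L])
  })
}

# n_sim productive CDR3 amino-acid sequences conditional on (v, j).
# Oversamples in adaptive chunks; errors if the pair never yields a
# productive sequence.
simulate_productive_vj <- function(model, v_gene, j_gene, n_sim,
                                   max_attempts = 60L) {
  out <- character(0)
  rate <- 0.25
  attempts <- 0L
  while (length(out) < n_sim) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("(", v_gene, ", ", j_gene,
           ") yields too few productive rearrangements")
    need <- n_sim - length(out)
    chunk <- min(2e6, max(2000L, ceiling(need / max(rate, 0.005)) + 100L))
    draw <- simulate_vj_raw(model, v_gene, j_gene, chunk)
    rate <- 0.5 * rate + 0.5 * mean(draw$productive)
    out <- c(out, draw$cdr3aa[draw$productive])
  }
  out[seq_len(n_sim)]
}

# ---- ball Pgen --------------------------------------------------------

#' Monte-Carlo generation probability of a CDR3 neighborhood
#'
#' Estimates, conditional on a (V, J) pair and on productivity, the
#' probability that the recombination model emits an amino-acid CDR3
#' inside the Hamming-distance-at-most-1 ball of `cdr3_aa` (same length,
#' at most one mismatch, the center itself included). `n_sim` productive
#' sequences are simulated in `n_batches` batches; the pooled fraction
#' is the point estimate and the between-batch spread gives the
#' standard error.
#'
#' @param model a `recomb_model`.
#' @param cdr3_aa query amino-acid CDR3.
#' @param v_gene,j_gene conditioning pair; must be in the model support.
#' @param n_sim total number of productive simulations (>= 1).
#' @param n_batches number of Monte-Carlo batches (>= 1).
#' @param seed integer seed.
#' @return an object of class `pgen_estimate` with fields `point`,
#'   `std_error`, `n_sim`, `n_batches`.
#' @export
estimate_ball_pgen <- function(model, cdr3_aa, v_gene, j_gene,
                               n_sim = 10000, n_batches = 20, seed = NULL) {
  if (!is_count_scalar(n_sim) || n_sim < 1) stop("n_sim must be >= 1")
  if (!is_count_scalar(n_batches) || n_batches < 1)
    stop("n_batches must be >= 1")
  if (!nrow(model$vj_usage[v == v_gene & j == j_gene]))
    stop("(", v_gene, ", ", j_gene, ") absent from model support")
  sims <- with_seed(seed,
                    simulate_productive_vj(model, v_gene, j_gene, n_sim))
  batch <- rep(seq_len(n_batches), length.out = n_sim)
  same_len <- nchar(sims) == nchar(cdr3_aa)
  in_ball <- logical(n_sim)
  if (any(same_len))
    in_ball[same_len] <- mismatch_count(sims[same_len], cdr3_aa) <= 1L
  point <- mean(in_ball)
  bf <- tapply(in_ball, batch, mean)
  se <- if (n_batches > 1) stats::sd(bf) / sqrt(n_batches) else 0
  structure(list(point = point, std_error = as.numeric(se),
                 n_sim = n_sim, n_batches = n_batches),
            class = "pgen_estimate")
}

#' @export
print.pgen_estimate <- function(x, ...) {
  cat(sprintf("<pgen_estimate> %.4g +/- %.2g (n_sim=%d, %d batches)\n",
              x$point, x$std_error, x$n_sim, x$n_batches))
  invisible(x)
}

#' Enumerate every rearrangement of a (V, J) pair
#'
#' Brute-force oracle: lists each (V deletion, J deletion, insert
#' length, insert sequence) event with its exact probability, its
#' nucleotide and (when in-frame) amino-acid sequence, and the
#' productivity flag. Probabilities over all events sum to 1.
#'
#' @param model a `recomb_model`.
#' @param v_gene,j_gene the conditioning pair.
#' @param max_events refuse models whose event count exceeds this bound.
#' @return data.table(cdr3nt, cdr3aa, prob, productive).
#' @export
enumerate_rearrangements <- function(model, v_gene, j_gene,
                                     max_events = 1e7) {
  vseq <- model$v_segments[[v_gene]]
  jseq <- model$j_segments[[j_gene]]
  if (is.null(vseq) || is.null(jseq))
    stop("(", v_gene, ", ", j_gene, ") not in model segment tables")
  ins_lens <- seq_along(model$insertion_length_dist) - 1L
  n_events <- length(model$v_deletion_dist) *
    length(model$j_deletion_dist) * sum(4^ins_lens)
  if (n_events > max_events)
    stop("enumeration bound exceeded: ", format(n_events, big.mark = ","),
         " events")
  bases <- c("A", "C", "G", "T")
  pieces <- lapply(ins_lens, function(L) {
    p_len <- model$insertion_length_dist[L + 1L]
    if (p_len == 0) return(NULL)
    if (L == 0L)
      return(data.table::data.table(ins = "", p_ins = p_len))
    grid <- do.call(data.table::CJ, rep(list(bases), L))
    pr <- rep(p_len, nrow(grid))
    for (k in seq_len(L))
      pr <- pr * model$insertion_base_probs[grid[[k]]]
    data.table::data.table(ins = do.call(paste0, grid), p_ins = pr)
  })
  ins_dt <- data.table::rbindlist(pieces)
  vd <- data.table::data.table(
    vtrim = vapply(seq_along(model$v_deletion_dist) - 1L, function(d)
      substr(vseq, 1L, nchar(vseq) - d), ""),
    p_v = model$v_deletion_dist)
  jd <- data.table::data.table(
    jtrim = vapply(seq_along(model$j_deletion_dist) - 1L, function(d)
      substring(jseq, d + 1L), ""),
    p_j = model$j_deletion_dist)
  ev <- data.table::CJ(iv = seq_len(nrow(vd)), ij = seq_len(nrow(jd)),
                       ii = seq_len(nrow(ins_dt)))
  out <- data.table::data.table(
    cdr3nt = paste0(vd$vtrim[ev$iv], ins_dt$ins[ev$ii], jd$jtrim[ev$ij]),
    prob = vd$p_v[ev$iv] * jd$p_j[ev$ij] * ins_dt$p_ins[ev$ii])
  out <- out[prob > 0, .(prob = sum(prob)), by = cdr3nt]
  len <- nchar(out$cdr3nt)
  out[, cdr3aa := NA_character_]
  inframe <- len %% 3L == 0L & len > 0L
  if (any(inframe)) out[inframe, cdr3aa := translate_nt(cdr3nt)]
  out[, productive := !is.na(cdr3aa) & !grepl("*", cdr3aa, fixed = TRUE) &
        startsWith(cdr3aa, "C") &
        (endsWith(cdr3aa, "F") | endsWith(cdr3aa, "W"))]
  out[is.na(cdr3aa), cdr3aa := ""]
  out[]
}

#' Exact generation probability of a CDR3 neighborhood
#'
#' Exhaustive-enumeration counterpart of [estimate_ball_pgen()]:
#' probability mass, conditional on (V, J) and on productivity, of the
#' Hamming-distance-at-most-1 amino-acid ball around `cdr3_aa`.
#' Only feasible for toy models (see `max_events`).
#'
#' @inheritParams estimate_ball_pgen
#' @param max_events enumeration capacity bound.
#' @return a probability in [0, 1].
#' @export
exact_ball_pgen <- function(model, cdr3_aa, v_gene, j_gene,
                            max_events = 1e7) {
  ev <- enumerate_rearrangements(model, v_gene, j_gene, max_events)
  prod_mass <- sum(ev$prob[ev$productive])
  if (prod_mass == 0) return(0)
  aa <- ev[productive == TRUE, .(prob = sum(prob)), by = cdr3aa]
  same_len <- aa[nchar(cdr3aa) == nchar(cdr3_aa)]
  if (!nrow(same_len)) return(0)
  in_ball <- mismatch_count(same_len$cdr3aa, cdr3_aa) <= 1L
  sum(same_len$prob[in_ball]) / prod_mass
}

# ---- synthetic repertoires -------------------------------------------

# Draw counts >= 2 from the configured clone-size law.
draw_counts <- function(n, count_law = c("geometric", "power_law"),
                        law_params = list()) {
  count_law <- match.arg(count_law)
  if (count_law == "geometric") {
    p <- law_params$p %||% 0.5
    2L + stats::rgeom(n, p)
  } else {
    alpha <- law_params$alpha %||% 2.5
    kmax <- law_params$kmax %||% 10000L
    k <- 2:kmax
    sample(k, n, replace = TRUE, prob = k^(-alpha))
  }
}

#' Generate a null repertoire from the recombination model
#'
#' Draws rearrangements from the model until `n_clonotypes` unique
#' (CDR3aa, V, J) keys are obtained, then assigns clone sizes (counts
#' of at least 2, so subsequent singleton removal is a no-op) from the
#' chosen law and normalizes frequencies.
#'
#' @param model a `recomb_model`.
#' @param n_clonotypes number of unique clonotypes to draw.
#' @param count_law `"geometric"` (count = 2 + Geom(p)) or
#'   `"power_law"` (P(count = k) proportional to k^-alpha, k >= 2).
#' @param law_params list of law parameters (`p` = 0.5, `alpha` = 2.5).
#' @param seed integer seed.
#' @param sample_id sample id of the generated repertoire.
#' @return a `tcr_repertoire`.
#' @export
generate_null_repertoire <- function(model, n_clonotypes,
                                     count_law = c("geometric", "power_law"),
                                     law_params = list(), seed = NULL,
                                     sample_id = "null") {
  if (!is_count_scalar(n_clonotypes) || n_clonotypes < 1)
    stop("n_clonotypes must be >= 1")
  count_law <- match.arg(count_law)
  with_seed(seed, {
    seen <- data.table::data.table(cdr3nt = character(),
                                   cdr3aa = character(),
                                   v = character(), j = character())
    stall <- 0L
    while (nrow(seen) < n_clonotypes) {
      need <- n_clonotypes - nrow(seen)
      n_draw <- max(2000L, 4L * need)
      k <- sample.int(nrow(model$vj_usage), n_draw, replace = TRUE,
                      prob = model$vj_usage$prob)
      pair_dt <- data.table::data.table(k = k)[, .(n = .N), by = k]
      chunks <- lapply(seq_len(nrow(pair_dt)), function(i) {
        vi <- model$vj_usage$v[pair_dt$k[i]]
        ji <- model$vj_usage$j[pair_dt$k[i]]
        d <- simulate_vj_raw(model, vi, ji, pair_dt$n[i])
        d <- d[productive == TRUE, .(cdr3nt, cdr3aa)]
        d[, `:=`(v = rep(vi, .N), j = rep(ji, .N))]
        d
      })
      before <- nrow(seen)
      seen <- unique(data.table::rbindlist(c(list(seen), chunks)),
                     by = c("cdr3aa", "v", "j"))
      stall <- if (nrow(seen) == before) stall + 1L else 0L
      if (stall >= 25L)
        stop("model support appears smaller than n_clonotypes = ",
             n_clonotypes)
    }
    seen <- seen[seq_len(n_clonotypes)]
    seen[, count := draw_counts(.N, count_law, law_params)]
    seen[, freq := count / sum(count)]
    repertoire(seen, sample_id = sample_id,
               metadata = list(origin = "null_model"),
               recompute_freq = FALSE)
  })
}

#' Plant a convergent low-Pgen cluster into a repertoire
#'
#' Emulates an antigen-selected convergent clone group: picks a seed
#' CDR3 from the bottom decile of ball Pgen among model-drawn candidates
#' (antigen-selected clusters sit where the null predicts few
#' neighbors), then adds the seed plus `cluster_size` single-substitution
#' variants at distinct central positions (4..L-3, 1-based), all sharing
#' the seed's (V, J). The planted clonotypes jointly receive frequency
#' `target_freq`; pre-existing clonotypes are scaled down by
#' `1 - target_freq`. Planted read counts are set to at least 2 so the
#' cluster survives singleton removal.
#'
#' @param rep a `tcr_repertoire` to augment.
#' @param model a `recomb_model`.
#' @param cluster_size number of variants around the seed (>= 2).
#' @param target_freq total frequency of the planted clonotypes (< 1).
#' @param seed integer seed.
#' @param n_candidates candidate pool size for the low-Pgen seed search.
#' @param vj optional c(v, j) pair to plant in; defaults to a usage draw.
#' @param min_len minimum CDR3 amino-acid length of the seed.
#' @return list(repertoire, truth) where `truth` is a
#'   data.table(cdr3aa, v, j, cluster_id, role) of planted clonotypes.
#' @export
plant_convergent_cluster <- function(rep, model, cluster_size,
                                     target_freq, seed = NULL,
                                     n_candidates = 200, vj = NULL,
                                     min_len = 9L) {
  if (!is_count_scalar(cluster_size) || cluster_size < 2)
    stop("cluster_size must be >= 2")
  if (target_freq <= 0 || target_freq >= 1)
    stop("target_freq must be in (0, 1)")
  with_seed(seed, {
    pool <- NULL
    for (try in seq_len(25L)) {
      if (is.null(vj) || try > 1L) {
        k <- sample.int(nrow(model$vj_usage), 1L,
                        prob = model$vj_usage$prob)
        vj <- c(model$vj_usage$v[k], model$vj_usage$j[k])
      }
      pool <- tryCatch(
        simulate_productive_vj(model, vj[1L], vj[2L],
                               max(5000L, 20L * n_candidates)),
        error = function(e) NULL)
      if (!is.null(pool)) break
    }
    if (is.null(pool))
      stop("no (V, J) pair with sufficient productive output")
    cand <- unique(pool[nchar(pool) >= min_len])
    if (length(cand) < 10L)
      stop("too few candidate seeds of length >= ", min_len)
    cand <- cand[seq_len(min(length(cand), n_candidates))]
    # ball Pgen of each candidate estimated against the shared pool
    ball <- vapply(cand, function(s) {
      same <- pool[nchar(pool) == nchar(s)]
      mean(nchar(pool) == nchar(s)) *
        (if (length(same)) mean(mismatch_count(same, s) <= 1L) else 0)
    }, 0)
    dec <- cand[ball <= stats::quantile(ball, 0.1)]
    seed_aa <- sort(dec)[1L]
    L <- nchar(seed_aa)
    central <- seq(4L, L - 3L)
    grid <- data.table::CJ(pos = central, res = AA20)
    grid <- grid[res != substring(seed_aa, pos, pos)]
    # prefer distinct positions: order variants round-robin over positions
    grid[, rank := seq_len(.N), by = pos]
    data.table::setorder(grid, rank, pos, res)
    if (cluster_size > nrow(grid))
      stop("cluster_size exceeds available central variants (",
           nrow(grid), ")")
    picks <- grid[seq_len(cluster_size)]
    variants <- vapply(seq_len(cluster_size), function(i) {
      s <- seed_aa
      substr(s, picks$pos[i], picks$pos[i]) <- picks$res[i]
      s
    }, "")
    planted <- data.table::data.table(
      cdr3aa = c(seed_aa, variants), v = vj[1L], j = vj[2L],
      role = c("seed", rep("variant", cluster_size)))
    cluster_id <- clonotype_key(seed_aa, vj[1L], vj[2L])
    planted[, cluster_id := cluster_id]

    base <- data.table::copy(rep$clonotypes)
    base <- base[!clonotype_key(cdr3aa, v, j) %in%
                   clonotype_key(planted$cdr3aa, planted$v, planted$j)]
    tot_bg <- sum(base$count)
    new_total <- max(tot_bg + 2L * nrow(planted),
                     round(tot_bg / (1 - target_freq)))
    pl_counts <- pmax(2L, round(target_freq * new_total / nrow(planted)))
    pl <- data.table::data.table(
      count = rep(pl_counts, nrow(planted)), cdr3nt = ".",
      cdr3aa = planted$cdr3aa, v = planted$v, d = ".", j = planted$j)
    pl[, freq := target_freq / nrow(planted)]
    base[, freq := if (tot_bg > 0) (1 - target_freq) * count / tot_bg
         else 0]
    dt <- data.table::rbindlist(list(
      base[, .(count, freq, cdr3nt, cdr3aa, v, d, j)],
      pl[, .(count, freq, cdr3nt, cdr3aa, v, d, j)]))
    out <- repertoire(dt, sample_id = rep$sample_id,
                      metadata = rep$metadata, recompute_freq = FALSE)
    list(repertoire = out,
         truth = planted[, .(cdr3aa, v, j, cluster_id, role)])
  })
}
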
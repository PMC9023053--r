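# alice_stat: neighbor-enrichment test against the recombination null.
#
# A clonotype is a "hit" when its count of Hamming-distance-1 neighbors
# (same V, same J, same CDR3 length) significantly exceeds the Poisson
# expectation derived from the Monte-Carlo generation probability of its
# amino-acid neighborhood.

#' Observed neighbor counts
#'
#' For every clonotype, counts the other clonotypes with identical
#' (V, J), identical CDR3 length, and Hamming distance at most 1
#' between amino-acid sequences. Computed with the position-masking
#' hash-bucket method (linear in total sequence length). Within a
#' (V, J) class amino-acid sequences are unique by the identity key,
#' so distance-0 neighbors cannot occur here (contrast the similarity
#' graph, which relaxes the V/J requirement).
#'
#' @param rep a `tcr_repertoire`, deduplicated on the clonotype key.
#' @return data.table(cdr3aa, v, j, d_obs) in the input row order.
#' @export
count_neighbors <- function(rep) {
  dt <- rep$clonotypes[, .(cdr3aa, v, j)]
  if (anyDuplicated(dt))
    stop("repertoire has duplicated clonotype keys; pool first")
  out <- data.table::copy(dt)
  out[, d_obs := 0L]
  if (!nrow(out)) return(out[])
  out[, len := nchar(cdr3aa)]
  out[, row_id := .I]
  grp <- split(seq_len(nrow(out)),
               paste(out$v, out$j, out$len, sep = "\r"))
  for (idx in grp) {
    if (length(idx) < 2L) next
    mt <- masked_table(out$cdr3aa[idx])
    mt[, bucket := .N, by = .(pos, masked)]
    d <- mt[, .(d = sum(bucket - 1L)), by = idx][order(idx)]
    out[idx, d_obs := d$d]
  }
  out[, `:=`(len = NULL, row_id = NULL)]
  out[]
}

#' Upper-tail Poisson neighbor p-value
#'
#' `P(X >= d_obs)` for `X ~ Poisson(lambda_expected)`; by convention 1
#' when `d_obs = 0` (the event is certain).
#'
#' @param d_obs observed neighbor count(s), non-negative integers.
#' @param lambda_expected null expectation(s), non-negative.
#' @return p-value vector.
#' @export
neighbor_pvalue <- function(d_obs, lambda_expected) {
  if (any(d_obs < 0) || any(lambda_expected < 0, na.rm = TRUE))
    stop("d_obs and lambda_expected must be non-negative")
  p <- stats::ppois(d_obs - 1, lambda_expected, lower.tail = FALSE)
  p[d_obs == 0] <- 1
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up adjusted p-values (monotone-enforced, capped at 1),
#' returned in the input order.
#'
#' @param p_values vector of p-values in [0, 1].
#' @return adjusted q-values.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m <= 1L) return(p_values)
  o <- order(p_values, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p_values[o]))
  q[order(o)]
}

# One (V, J) class's cached simulation pool plus lazily-built
# aggregates: exact-sequence counts and per-length masked buckets.
class_sim_entry <- function(model, v_gene, j_gene, n_sim, n_batches,
                            seed, cache = NULL) {
  cache_key <- paste(v_gene, j_gene, n_sim, n_batches, seed, sep = "\r")
  if (!is.null(cache) && !is.null(cache[[cache_key]]))
    return(cache[[cache_key]])
  sims <- with_seed(seed,
                    simulate_productive_vj(model, v_gene, j_gene, n_sim))
  batch <- rep(seq_len(n_batches), length.out = n_sim)
  e <- new.env(parent = emptyenv())
  e$sims <- sims
  e$batch <- batch
  e$batch_size <- tabulate(batch, n_batches)
  e$sim_len <- nchar(sims)
  e$ex <- data.table::data.table(cdr3aa = sims, batch = batch)[
    , .(n_exact = .N), by = .(cdr3aa, batch)]
  data.table::setkey(e$ex, cdr3aa)
  e$buckets <- list()
  if (!is.null(cache)) cache[[cache_key]] <- e
  e
}

class_sim_buckets <- function(e, L) {
  kL <- as.character(L)
  b <- e$buckets[[kL]]
  if (is.null(b)) {
    sel <- e$sim_len == L
    if (!any(sel)) {
      b <- data.table::data.table(pos = integer(), masked = character(),
                                  batch = integer(), n = integer())
    } else {
      sm <- masked_table(e$sims[sel])
      sm[, batch := e$batch[sel][idx]]
      b <- sm[, .(n = .N), by = .(pos, masked, batch)]
    }
    data.table::setkey(b, pos, masked)
    e$buckets[[kL]] <- b
  }
  b
}

# Monte-Carlo ball/point Pgen of several same-class queries against one
# shared simulation pool. Returns per-query totals and per-batch counts.
class_ball_stats <- function(model, v_gene, j_gene, queries, n_sim,
                             n_batches, seed, cache = NULL) {
  e <- class_sim_entry(model, v_gene, j_gene, n_sim, n_batches, seed,
                       cache)
  qdt <- data.table::data.table(qidx = seq_along(queries),
                                cdr3aa = queries,
                                len = nchar(queries))
  # exact (point) counts per query and batch
  exact_counts <- matrix(0, nrow(qdt), n_batches)
  hit <- e$ex[qdt, on = "cdr3aa", nomatch = 0L]
  if (nrow(hit)) exact_counts[cbind(hit$qidx, hit$batch)] <- hit$n_exact
  # ball counts via position masking, per CDR3 length
  ball_counts <- matrix(0, nrow(qdt), n_batches)
  for (L in unique(qdt$len)) {
    buckets <- class_sim_buckets(e, L)
    qsub <- qdt[len == L]
    qrows <- qsub$qidx
    if (nrow(buckets)) {
      qmask <- masked_table(qsub$cdr3aa)
      qmask[, qidx := qsub$qidx[idx]]
      jn <- buckets[qmask, on = c("pos", "masked"), nomatch = 0L,
                    allow.cartesian = TRUE]
      if (nrow(jn)) {
        agg <- jn[, .(s = sum(n)), by = .(qidx, batch)]
        ball_counts[cbind(agg$qidx, agg$batch)] <- agg$s
      }
      ball_counts[qrows, ] <- ball_counts[qrows, , drop = FALSE] -
        (L - 1L) * exact_counts[qrows, , drop = FALSE]
    }
  }
  list(queries = qdt$cdr3aa,
       ball = rowSums(ball_counts) / n_sim,
       point = rowSums(exact_counts) / n_sim,
       ball_batch = sweep(ball_counts, 2L, e$batch_size, "/"),
       point_batch = sweep(exact_counts, 2L, e$batch_size, "/"),
       n_batches = n_batches)
}

#' Run the neighbor-enrichment test on a repertoire
#'
#' Singletons are removed first (the reduction is reported via
#' `message()`). For clonotype i in a (V, J) class of size `N_vj`, the
#' null expectation of its neighbor count is
#' `lambda = q_factor * (N_vj - 1) * (ball_pgen - point_pgen)`, where
#' `ball_pgen` is the Monte-Carlo generation probability of the
#' Hamming-distance-at-most-1 amino-acid neighborhood (center included)
#' and `point_pgen` the mass of the center itself, both conditional on
#' the (V, J) pair and on productivity; the subtraction makes the
#' expectation count neighbors rather than the whole ball. P-values are
#' upper-tail Poisson, adjusted jointly across all tested clonotypes by
#' Benjamini-Hochberg; hits satisfy `q < alpha`.
#'
#' Because a clonotype with zero observed neighbors has p-value 1
#' regardless of `lambda`, simulations are by default only run for
#' (V, J) classes containing at least one neighbor pair; other rows get
#' `lambda = NA`. Set `full = TRUE` to compute every expectation.
#'
#' @param rep a `tcr_repertoire` (singletons removed internally).
#' @param model a `recomb_model`.
#' @param alpha BH-adjusted significance threshold (default 0.001).
#' @param n_sim productive Monte-Carlo simulations per (V, J) class.
#' @param n_batches Monte-Carlo batches for the standard error.
#' @param q_factor multiplicative calibration constant for selection
#'   attrition (default 1), or `"auto"` to self-calibrate so that the
#'   median observed/expected ratio over low-Pgen clonotypes with
#'   positive expectation is 1 (falls back to 1 when degenerate).
#' @param seed master seed; each (V, J) class derives its own sub-seed,
#'   so results do not depend on class processing order.
#' @param full compute `lambda` for all clonotypes, not only those in
#'   classes with observed neighbors.
#' @param cache optional environment reusing simulation pools across
#'   calls with the same model/seed (used by the pipeline).
#' @return data.table(cdr3aa, v, j, count, freq, d_obs, ball_pgen,
#'   ball_se, point_pgen, lambda, p_value, q_value, is_hit) sorted by
#'   q-value then key, with attributes `n_input` (clonotypes before
#'   singleton removal) and `n_tested`.
#' @export
run_alice <- function(rep, model, alpha = 0.001, n_sim = 20000,
                      n_batches = 20, q_factor = 1.0, seed = NULL,
                      full = FALSE, cache = NULL) {
  n_input <- n_clonotypes(rep)
  rep_f <- remove_singletons(rep)
  message(sprintf("singleton removal: %d -> %d clonotypes",
                  n_input, n_clonotypes(rep_f)))
  auto_q <- identical(q_factor, "auto")
  if (auto_q) full <- TRUE
  nb <- count_neighbors(rep_f)
  res <- data.table::copy(rep_f$clonotypes[, .(cdr3aa, v, j, count, freq)])
  res[, d_obs := nb$d_obs]
  supported <- res[paste(v, j) %in%
                     paste(model$vj_usage$v, model$vj_usage$j)]
  n_skip <- nrow(res) - nrow(supported)
  if (n_skip > 0)
    warning(n_skip, " clonotype(s) in (V, J) classes absent from the ",
            "model were skipped")
  res <- supported
  res[, `:=`(ball_pgen = NA_real_, ball_se = NA_real_,
             point_pgen = NA_real_, lambda = NA_real_,
             lambda_se = NA_real_)]
  if (nrow(res)) {
    res[, N_vj := .N, by = .(v, j)]
    need <- res[, .(go = full || any(d_obs > 0L)), by = .(v, j)][go == TRUE]
    for (i in seq_len(nrow(need))) {
      vi <- need$v[i]; ji <- need$j[i]
      rows <- which(res$v == vi & res$j == ji)
      st <- class_ball_stats(model, vi, ji, res$cdr3aa[rows], n_sim,
                             n_batches,
                             seed = derive_seed(seed %||% 0,
                                                paste(vi, ji)),
                             cache = cache)
      nvj <- res$N_vj[rows[1L]]
      lam_b <- (nvj - 1L) * (st$ball_batch - st$point_batch)
      res[rows, `:=`(
        ball_pgen = st$ball,
        ball_se = apply(st$ball_batch, 1L, stats::sd) /
          sqrt(st$n_batches),
        point_pgen = st$point,
        lambda = (nvj - 1L) * (st$ball - st$point),
        lambda_se = apply(lam_b, 1L, stats::sd) / sqrt(st$n_batches))]
    }
    if (auto_q) {
      lowp <- res[!is.na(ball_pgen) & lambda > 0 &
                    ball_pgen <= stats::median(ball_pgen, na.rm = TRUE)]
      q_factor <- if (nrow(lowp)) stats::median(lowp$d_obs / lowp$lambda)
                  else 1
      if (!is.finite(q_factor) || q_factor <= 0) {
        warning("q_factor self-calibration degenerate; using 1")
        q_factor <- 1
      }
      message(sprintf("self-calibrated q_factor = %.3g", q_factor))
    }
    res[, lambda := q_factor * lambda]
    res[, lambda_se := q_factor * lambda_se]
    res[, p_value := 1.0]
    has_l <- !is.na(res$lambda)
    res[has_l, p_value := neighbor_pvalue(d_obs, pmax(lambda, 0))]
    res[, q_value := bh_adjust(p_value)]
    res[, is_hit := q_value < alpha]
    res[, N_vj := NULL]
    data.table::setorder(res, q_value, cdr3aa, v, j)
  } else {
    res[, `:=`(p_value = numeric(0), q_value = numeric(0),
               is_hit = logical(0))]
  }
  data.table::setattr(res, "n_input", n_input)
  data.table::setattr(res, "n_tested", nrow(res))
  res[]
}

#' Normalized hit count
#'
#' Number of neighbor-test hits divided by the number of clonotypes in
#' the initial input (counted *before* singleton removal), making hit
#' counts comparable across repertoires of different depth.
#'
#' @param results output of [run_alice()].
#' @param n_input_clonotypes clonotype count of the original input;
#'   defaults to the attribute stored by [run_alice()].
#' @return a fraction.
#' @export
normalized_hits <- function(results,
                            n_input_clonotypes = attr(results, "n_input")) {
  if (is.null(n_input_clonotypes) || n_input_clonotypes < 1)
    stop("n_input_clonotypes must be >= 1")
  sum(results$is_hit) / n_input_clonotypes
}
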
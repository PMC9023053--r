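# expansion: replicate-based differential clonotype expansion between
# two culture conditions, as a self-contained negative binomial exact
# test (median-of-ratios normalization, method-of-moments dispersion
# with trended shrinkage, conditional two-group exact test). The
# calling thresholds are FDR-adjusted p < 0.01 and log2 fold-change > 1.

#' Construct a clonotype count matrix
#'
#' @param counts integer matrix, rows = clonotype keys (rownames),
#'   columns = samples (colnames).
#' @param conditions character vector of condition labels, one per
#'   column.
#' @return an object of class `tcr_count_matrix` with fields `counts`,
#'   `samples` (data.table(sample, condition)), `library_sizes`.
#' @export
count_matrix <- function(counts, conditions) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row and column names")
  if (length(conditions) != ncol(counts))
    stop("one condition label per column required")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  structure(list(counts = counts,
                 samples = data.table::data.table(
                   sample = colnames(counts),
                   condition = as.character(conditions)),
                 library_sizes = colSums(counts)),
            class = "tcr_count_matrix")
}

#' @export
print.tcr_count_matrix <- function(x, ...) {
  cat(sprintf("<tcr_count_matrix> %d clonotypes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$condition), collapse = " vs ")))
  invisible(x)
}

#' Read / write a count matrix with its design
#'
#' The counts TSV has a `key` column (clonotype `cdr3aa|V|J`) followed
#' by one integer column per sample; the design TSV has columns
#' `sample`, `condition`.
#'
#' @param counts_path,design_path TSV paths.
#' @return a `tcr_count_matrix`.
#' @export
read_count_matrix <- function(counts_path, design_path) {
  ct <- data.table::fread(counts_path, sep = "\t", header = TRUE)
  if (names(ct)[1L] != "key") stop("first counts column must be 'key'")
  des <- data.table::fread(design_path, sep = "\t", header = TRUE)
  if (!all(c("sample", "condition") %in% names(des)))
    stop("design needs columns sample, condition")
  m <- as.matrix(ct[, -1L])
  rownames(m) <- ct$key
  if (!all(colnames(m) %in% des$sample))
    stop("design is missing sample(s): ",
         paste(setdiff(colnames(m), des$sample), collapse = ", "))
  count_matrix(m, des$condition[match(colnames(m), des$sample)])
}

#' @rdname read_count_matrix
#' @param m a `tcr_count_matrix`.
#' @export
write_count_matrix <- function(m, counts_path, design_path) {
  dt <- data.table::as.data.table(list(key = rownames(m$counts)))
  for (s in colnames(m$counts)) dt[, (s) := m$counts[, s]]
  data.table::fwrite(dt, counts_path, sep = "\t")
  data.table::fwrite(m$samples, design_path, sep = "\t")
  invisible(counts_path)
}

#' Median-of-ratios library normalization
#'
#' Each column's factor is the median, over rows with all-positive
#' counts, of the ratio of its count to the row geometric mean;
#' factors are rescaled to geometric mean 1. Effective library size =
#' library size x factor. With no all-positive row the factors default
#' to 1 with a warning.
#'
#' @param m a `tcr_count_matrix`.
#' @return list(factors, effective_sizes), both named by sample.
#' @export
normalize_libraries <- function(m) {
  ct <- m$counts
  pos <- rowSums(ct > 0) == ncol(ct)
  if (!any(pos)) {
    warning("no all-positive row; normalization factors set to 1")
    f <- rep(1, ncol(ct))
  } else {
    lref <- rowMeans(log(ct[pos, , drop = FALSE]))
    f <- apply(ct[pos, , drop = FALSE], 2L,
               function(col) stats::median(exp(log(col) - lref)))
    f <- f / exp(mean(log(f)))
  }
  names(f) <- colnames(ct)
  list(factors = f, effective_sizes = m$library_sizes * f)
}

#' Method-of-moments dispersion with trended shrinkage
#'
#' Per clonotype, dispersion is estimated from within-condition mean
#' and variance of normalized counts (`phi = (var - mu) / mu^2`, pooled
#' across conditions with replication), then shrunk 50/50 toward the
#' median dispersion of its abundance bin and floored at `1e-6`.
#'
#' @param m a `tcr_count_matrix`.
#' @param n_bins abundance bins for the trend (default 10).
#' @return named numeric vector of dispersions (one per clonotype).
#' @export
estimate_dispersion <- function(m, n_bins = 10L) {
  cond <- m$samples$condition
  reps <- table(cond)
  if (all(reps < 2))
    stop("no condition has >= 2 replicates; supply dispersions manually")
  nf <- normalize_libraries(m)
  eff <- nf$effective_sizes
  sc <- exp(mean(log(pmax(eff, 1)))) / pmax(eff, 1)
  norm <- sweep(m$counts, 2L, sc, "*")
  num <- rep(0, nrow(norm)); den <- rep(0, nrow(norm))
  for (cc in names(reps)[reps >= 2]) {
    cols <- which(cond == cc)
    mu <- rowMeans(norm[, cols, drop = FALSE])
    v <- apply(norm[, cols, drop = FALSE], 1L, stats::var)
    w <- length(cols) - 1L
    ok <- mu > 0
    num[ok] <- num[ok] + w * (v[ok] - mu[ok]) / mu[ok]^2
    den <- den + w
  }
  raw <- pmax(num / den, 0)
  ab <- rowMeans(norm)
  bin <- cut(rank(ab, ties.method = "first"),
             breaks = n_bins, labels = FALSE)
  trend <- stats::ave(raw, bin, FUN = stats::median)
  phi <- pmax(0.5 * raw + 0.5 * trend, 1e-6)
  names(phi) <- rownames(m$counts)
  phi
}

# Conditional two-group exact test for one clonotype.
# sa, sb: integer group pseudo-sums; na, nb: replicate numbers;
# phi: dispersion. Returns the doubled-smaller-tail two-sided p.
nb_exact_pvalue <- function(sa, sb, na, nb, phi) {
  t <- sa + sb
  if (t == 0L) return(1)
  mu <- t / (na + nb)
  s <- 0:t
  if (phi < 1e-12) {
    # Poisson limit: conditional law is binomial(t, na/(na+nb))
    logw <- stats::dbinom(s, t, na / (na + nb), log = TRUE)
  } else {
    logw <- stats::dnbinom(s, size = na / phi, mu = na * mu,
                           log = TRUE) +
      stats::dnbinom(t - s, size = nb / phi, mu = nb * mu, log = TRUE)
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  lo <- sum(w[s <= sa])
  hi <- sum(w[s >= sa])
  min(1, 2 * min(lo, hi))
}

#' Negative binomial exact test for differential expansion
#'
#' Two-condition test per clonotype: effective library sizes are
#' equalized by rescaling counts to a common size (pseudocounts,
#' rounded group sums), and the group sums are compared with a
#' conditional negative binomial exact test (the two-sided p-value is
#' the doubled smaller tail). Log2 fold-changes are computed from
#' normalized per-replicate means with a 0.5 pseudo-count, focal
#' condition over reference. Benjamini-Hochberg adjustment is applied
#' across clonotypes; a clonotype is called expanded when
#' `q < fdr` and `log2fc > lfc`.
#'
#' @param m a `tcr_count_matrix` with exactly two condition labels.
#' @param focal the condition whose expansion is being called; the
#'   other condition is the reference.
#' @param dispersions optional per-clonotype dispersion vector;
#'   defaults to [estimate_dispersion()]. Dispersion 0 invokes the
#'   exact Poisson-limit (binomial) test.
#' @param fdr,lfc calling thresholds (defaults 0.01 and 1).
#' @return data.table(key, mean_ref, mean_focal, log2fc, p_value,
#'   q_value, called) in input row order.
#' @export
nb_exact_test <- function(m, focal, dispersions = NULL,
                          fdr = 0.01, lfc = 1.0) {
  conds <- unique(m$samples$condition)
  if (length(conds) != 2L)
    stop("exactly two condition labels required (got ",
         length(conds), ")")
  if (!focal %in% conds) stop("unknown focal condition: ", focal)
  ref <- setdiff(conds, focal)
  ca <- which(m$samples$condition == ref)
  cb <- which(m$samples$condition == focal)
  if (!length(ca) || !length(cb))
    stop("a condition has zero samples")
  if (is.null(dispersions)) dispersions <- estimate_dispersion(m)
  if (length(dispersions) == 1L)
    dispersions <- rep(dispersions, nrow(m$counts))
  nf <- normalize_libraries(m)
  eff <- pmax(nf$effective_sizes, 1)
  common <- exp(mean(log(eff)))
  pseudo <- sweep(m$counts, 2L, common / eff, "*")
  sa <- round(rowSums(pseudo[, ca, drop = FALSE]))
  sb <- round(rowSums(pseudo[, cb, drop = FALSE]))
  na <- length(ca); nb <- length(cb)
  p <- vapply(seq_len(nrow(m$counts)), function(g)
    nb_exact_pvalue(sa[g], sb[g], na, nb, dispersions[g]), 0)
  mean_ref <- rowMeans(pseudo[, ca, drop = FALSE])
  mean_focal <- rowMeans(pseudo[, cb, drop = FALSE])
  log2fc <- log2((mean_focal + 0.5) / (mean_ref + 0.5))
  res <- data.table::as.data.table(list(
    key = rownames(m$counts),
    mean_ref = mean_ref, mean_focal = mean_focal,
    log2fc = log2fc, p_value = p, q_value = bh_adjust(p)))
  res[, called := q_value < fdr & log2fc > lfc]
  res[]
}

#' Expanded clonotype calls
#'
#' Keys with `q < fdr` and `log2fc > lfc` (expansion in the focal
#' condition; one-sided direction on a two-sided p-value, matching the
#' reported calling rule).
#'
#' @param results output of [nb_exact_test()].
#' @param fdr,lfc thresholds (defaults 0.01 and 1).
#' @return character vector of called keys.
#' @export
call_expanded <- function(results, fdr = 0.01, lfc = 1.0) {
  results[q_value < fdr & log2fc > lfc, key]
}
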
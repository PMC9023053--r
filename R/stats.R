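# repertoire_stats: clonality and cross-repertoire matching readouts.

#' Repertoire clonality (1 - normalized Shannon-Wiener index)
#'
#' Shannon entropy `H = -sum(f * ln f)` over positive clonotype
#' frequencies, normalized by `ln(richness)`; clonality is its
#' complement. A uniform repertoire has clonality 0, a monoclonal one
#' has clonality 1 (richness-1 convention).
#'
#' @param rep a `tcr_repertoire`.
#' @return a `diversity_summary` list: `richness`, `shannon` (natural
#'   log), `normalized_shannon`, `clonality`.
#' @export
clonality <- function(rep) {
  f <- rep$clonotypes$freq
  f <- f[f > 0]
  if (!length(f)) stop("no clonotype with positive frequency")
  f <- f / sum(f)
  richness <- length(f)
  H <- -sum(f * log(f))
  norm <- if (richness >= 2) H / log(richness) else 0
  structure(list(richness = richness, shannon = H,
                 normalized_shannon = norm, clonality = 1 - norm),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(paste0("<diversity_summary> richness %d, shannon %.4f,",
                     " clonality %.4f\n"),
              x$richness, x$shannon, x$clonality))
  invisible(x)
}

#' Count query clonotypes among a reference repertoire's top clones
#'
#' How many of the query keys appear (by the `cdr3aa|V|J` key) among
#' the `top_n` reference clonotypes ranked by frequency (ties broken by
#' lexicographic key order).
#'
#' @param query_keys character vector of clonotype keys (see
#'   [repertoire_keys()]), or a data.frame with `cdr3aa`, `v`, `j`.
#' @param reference the reference `tcr_repertoire`.
#' @param top_n rank cutoff; `Inf` means the whole reference.
#' @return integer match count.
#' @export
subset_match_count <- function(query_keys, reference, top_n = Inf) {
  if (is.data.frame(query_keys)) {
    qk <- data.table::as.data.table(query_keys)
    query_keys <- clonotype_key(qk$cdr3aa, qk$v, qk$j)
  }
  if (!is.infinite(top_n) && (!is_count_scalar(top_n) || top_n < 1))
    stop("top_n must be >= 1")
  dt <- data.table::as.data.table(
    list(key = repertoire_keys(reference),
         freq = reference$clonotypes$freq))
  data.table::setorder(dt, -freq, key)
  top <- if (is.infinite(top_n)) dt$key else
    dt$key[seq_len(min(top_n, nrow(dt)))]
  sum(unique(query_keys) %in% top)
}
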
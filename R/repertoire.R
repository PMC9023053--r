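# repertoire_io: VDJtools-style clonotype tables and pre-processing.

VDJTOOLS_COLS <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j")
REQUIRED_COLS <- c("count", "freq", "cdr3aa", "v", "j")

#' Construct a TCR repertoire object
#'
#' A repertoire is one sample's table of clonotypes. Each clonotype is a
#' unique (CDR3 amino acid, V gene, J gene) triple carrying a read count
#' and a frequency. The nucleotide CDR3 is optional (written as `"."`
#' when absent), as is the D segment.
#'
#' @param clonotypes a `data.frame`/`data.table` with columns `count`,
#'   `freq`, `cdr3aa`, `v`, `j` and optionally `cdr3nt`, `d`.
#' @param sample_id sample identifier.
#' @param metadata named list of sample-level labels (subset, condition,
#'   patient, ...).
#' @param recompute_freq recompute `freq` from `count` when absent or
#'   inconsistent with the counts by more than `1e-6`.
#' @return an object of class `tcr_repertoire`.
#' @export
repertoire <- function(clonotypes, sample_id = "sample",
                       metadata = list(), recompute_freq = TRUE) {
  dt <- data.table::as.data.table(clonotypes)
  if (!nrow(dt)) {
    dt <- data.table::data.table(count = integer(), freq = numeric(),
                                 cdr3nt = character(), cdr3aa = character(),
                                 v = character(), d = character(),
                                 j = character())
  }
  miss <- setdiff(setdiff(REQUIRED_COLS, "freq"), names(dt))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!"cdr3nt" %in% names(dt)) dt[, cdr3nt := "."]
  if (!"d" %in% names(dt)) dt[, d := "."]
  if (!"freq" %in% names(dt)) dt[, freq := NA_real_]
  dt <- dt[, VDJTOOLS_COLS, with = FALSE]
  dt[, `:=`(cdr3nt = as.character(cdr3nt), cdr3aa = as.character(cdr3aa),
            v = strip_allele(as.character(v)), d = as.character(d),
            j = strip_allele(as.character(j)))]
  bad <- which(is.na(suppressWarnings(as.numeric(dt$count))) |
               as.numeric(dt$count) != floor(as.numeric(dt$count)))
  if (length(bad))
    stop("non-integer count at row ", bad[1L])
  dt[, count := as.integer(count)]
  if (any(dt$count < 0)) stop("negative read count")
  if (nrow(dt)) {
    if (any(!nzchar(dt$cdr3aa))) stop("empty CDR3 amino-acid sequence")
    if (any(grepl("\\*", dt$cdr3aa))) stop("stop codon in CDR3 amino acids")
    has_nt <- !is.na(dt$cdr3nt) & dt$cdr3nt != "." & nzchar(dt$cdr3nt)
    if (any(has_nt)) {
      tr <- translate_nt(dt$cdr3nt[has_nt])
      if (any(tr != dt$cdr3aa[has_nt]))
        stop("cdr3nt does not translate to cdr3aa at row ",
             which(has_nt)[which(tr != dt$cdr3aa[has_nt])[1L]])
    }
    tot <- sum(dt$count)
    if (recompute_freq) {
      inconsistent <- tot > 0 &&
        (anyNA(dt$freq) || max(abs(dt$freq - dt$count / tot)) > 1e-6)
      if (inconsistent) dt[, freq := count / tot]
      if (tot == 0 && anyNA(dt$freq)) dt[, freq := 0]
    }
  }
  structure(list(sample_id = sample_id, clonotypes = dt,
                 metadata = metadata),
            class = "tcr_repertoire")
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> sample '%s': %d clonotypes, %d reads\n",
              x$sample_id, nrow(x$clonotypes), total_reads(x)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of clonotypes in a repertoire
#' @param rep a `tcr_repertoire`.
#' @return integer count of clonotype rows.
#' @export
n_clonotypes <- function(rep) nrow(rep$clonotypes)

#' Total read count of a repertoire
#' @param rep a `tcr_repertoire`.
#' @return integer library size.
#' @export
total_reads <- function(rep) sum(rep$clonotypes$count)

#' Clonotype identity keys of a repertoire
#'
#' Keys are `cdr3aa|V|J` with allele suffixes stripped from the gene
#' labels; the nucleotide sequence is deliberately not part of the key.
#' @param rep a `tcr_repertoire`.
#' @return character vector of keys, one per clonotype row.
#' @export
repertoire_keys <- function(rep) {
  with(rep$clonotypes, clonotype_key(cdr3aa, v, j))
}

#' Read a clonotype table
#'
#' Reads a tab-separated VDJtools-style table with header columns
#' `count freq cdr3nt cdr3aa v d j` (the five columns `count`, `freq`,
#' `cdr3aa`, `v`, `j` are required; `cdr3nt` and `d` default to `"."`).
#' Frequencies are recomputed from counts when missing or off by more
#' than `1e-6`.
#'
#' @param path path to the TSV file.
#' @param dialect table dialect; only `"vdjtools"` is defined.
#' @param sample_id sample id; defaults to the file name without extension.
#' @param metadata named list of sample metadata.
#' @return a `tcr_repertoire`.
#' @export
read_repertoire <- function(path, dialect = c("vdjtools"),
                            sample_id = NULL, metadata = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- tolower(strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]])
  miss <- setdiff(setdiff(REQUIRED_COLS, "freq"), hdr)
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(
                            character = intersect(c("cdr3nt", "cdr3aa",
                                                    "v", "d", "j"), hdr)),
                          na.strings = NULL, fill = TRUE)
  names(dt) <- tolower(names(dt))
  repertoire(dt,
             sample_id = sample_id %||%
               sub("\\.[^.]*$", "", basename(path)),
             metadata = metadata)
}

#' Write a clonotype table
#'
#' Inverse of [read_repertoire()]: tab-separated, UTF-8, Unix newlines,
#' frequencies printed with 9 significant digits.
#'
#' @param rep a `tcr_repertoire`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_repertoire <- function(rep, path) {
  dt <- data.table::copy(rep$clonotypes)
  dt[, freq := formatC(freq, digits = 9, format = "g")]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(VDJTOOLS_COLS, collapse = "\t"), con, sep = "\n")
  if (nrow(dt))
    writeLines(do.call(paste, c(as.list(dt), sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Remove singleton clonotypes
#'
#' Drops all clonotypes with read count 1 or less and renormalizes the
#' surviving frequencies. Singletons are removed before neighbor testing
#' to exclude under-corrected erroneous variants that would otherwise
#' create false neighbors of abundant clonotypes.
#'
#' @param rep a `tcr_repertoire`.
#' @return a new `tcr_repertoire`; the input is not modified.
#' @export
remove_singletons <- function(rep) {
  dt <- rep$clonotypes[count > 1L]
  out <- data.table::copy(dt)
  tot <- sum(out$count)
  out[, freq := if (tot > 0) count / tot else numeric(nrow(out))]
  repertoire(out, sample_id = rep$sample_id, metadata = rep$metadata,
             recompute_freq = FALSE)
}

#' Down-sample a repertoire to a fixed read depth
#'
#' Samples `n_reads` reads without replacement from the read-level
#' multiset (multivariate hypergeometric), mirroring VDJtools-style
#' pre-processing. Deterministic given `seed`.
#'
#' @param rep a `tcr_repertoire`.
#' @param n_reads target total read count; must not exceed [total_reads()].
#' @param seed integer seed.
#' @return a new `tcr_repertoire` whose counts sum to `n_reads`
#'   (clonotypes sampled to zero are dropped).
#' @export
downsample <- function(rep, n_reads, seed = NULL) {
  tot <- total_reads(rep)
  if (!is_count_scalar(n_reads) || n_reads < 0)
    stop("n_reads must be a non-negative integer")
  if (n_reads > tot)
    stop("n_reads (", n_reads, ") exceeds total reads (", tot, ")")
  kept <- with_seed(seed, {
    reads <- rep.int(seq_len(nrow(rep$clonotypes)), rep$clonotypes$count)
    tabulate(reads[sample.int(length(reads), n_reads)],
             nbins = nrow(rep$clonotypes))
  })
  dt <- data.table::copy(rep$clonotypes)
  dt[, count := kept]
  dt <- dt[count > 0L]
  dt[, freq := count / sum(count)]
  repertoire(dt, sample_id = rep$sample_id, metadata = rep$metadata,
             recompute_freq = FALSE)
}

#' Pool repertoires
#'
#' Merges clonotypes across repertoires on the identity key
#' (`cdr3aa`, `v`, `j`), summing counts and renormalizing frequencies.
#' For merged rows the nucleotide CDR3 and D label of the most abundant
#' contributor are retained.
#'
#' @param reps list of `tcr_repertoire` objects (at least one).
#' @param sample_id id of the pooled sample.
#' @return a pooled `tcr_repertoire` with unique clonotype keys.
#' @export
pool_repertoires <- function(reps, sample_id = "pooled") {
  if (inherits(reps, "tcr_repertoire")) reps <- list(reps)
  if (!length(reps)) stop("at least one repertoire required")
  dt <- data.table::rbindlist(lapply(reps, `[[`, "clonotypes"))
  if (!nrow(dt)) return(repertoire(dt, sample_id = sample_id))
  data.table::setorder(dt, -count)
  pooled <- dt[, .(count = sum(count), cdr3nt = cdr3nt[1L], d = d[1L]),
               by = .(cdr3aa, v, j)]
  pooled[, freq := count / sum(count)]
  data.table::setorder(pooled, -count, cdr3aa, v, j)
  repertoire(pooled, sample_id = sample_id, recompute_freq = FALSE)
}
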
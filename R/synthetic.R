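# synthetic_data: packaged synthetic study emulating the shapes of a
# TIL sorting-and-culture experiment: a bulk tumor repertoire, sorted
# DP (CD39+PD-1+) and non-DP subsets with differential enrichment of
# planted convergent clusters, replicate count matrices across two
# culture conditions with planted clonal expansions, and a small
# specificity database that matches half of each planted cluster.
# Complete ground truth is returned (and written) alongside.

default_study_design <- function() {
  list(
    n_clonotypes = 3000,      # bulk background richness
    n_clusters = 3,           # planted convergent clusters
    cluster_size = 10,        # variants per cluster (plus the seed)
    cluster_freq = 0.008,     # per-cluster frequency in bulk / non-DP
    enrichment = 10,          # DP planted-frequency multiplier
    n_dp_background = 800,    # DP subset background richness (DP is
                              # oligoclonal: fewer unique clonotypes)
    n_nondp_background = 2500,
    subset_reads = 30000,     # read depth of the sorted subsets
    conditions = c("IL2_high", "IL21_IL2low_aPD1"),
    focal_condition = "IL21_IL2low_aPD1",
    n_replicates = 6,
    n_counted = 2000,         # clonotypes carried into the count matrix
    replicate_reads = 30000,  # expected reads per culture replicate
    n_expanded = 20,
    expansion_log2fc = 3,
    dispersion = 0.1)
}

# Antigen annotations used for the planted clusters (well-known
# HLA-A*02-restricted melanoma antigens; the epitopes are standard).
PLANTED_ANTIGENS <- data.frame(
  antigen = c("Melan-A", "NY-ESO-1", "gp100"),
  epitope = c("ELAGIGILTV", "SLLMWITQC", "KTWGQYWQV"),
  hla = c("A*02", "A*02:01", "A*02:01"),
  stringsAsFactors = FALSE)

# Patient allele list used by the synthetic study (a realistic
# HLA-A*02-positive six-allele genotype).
SYNTHETIC_PATIENT_HLA <- c("A*02:01", "A*26:01", "B*27:05", "B*73:01",
                           "C*02:02", "C*15:05")

# Subsample a planted repertoire to a sorted-subset read depth:
# multinomial reads over the given frequencies, planted members kept
# at count >= 2 so they survive singleton removal.
sample_subset <- function(freq_dt, planted_keys, n_reads, sample_id,
                          metadata) {
  counts <- as.vector(stats::rmultinom(1L, n_reads, freq_dt$freq))
  dt <- data.table::copy(freq_dt)
  dt[, count := counts]
  planted <- clonotype_key(dt$cdr3aa, dt$v, dt$j) %in% planted_keys
  dt[planted & count < 2L, count := 2L]
  dt <- dt[count > 0L]
  dt[, freq := count / sum(count)]
  repertoire(dt[, .(count, freq, cdr3nt, cdr3aa, v, d, j)],
             sample_id = sample_id, metadata = metadata,
             recompute_freq = FALSE)
}

#' Generate a complete synthetic study with ground truth
#'
#' Produces (a) a bulk repertoire drawn from the recombination model
#' with `n_clusters` planted convergent low-Pgen clusters, (b) paired
#' DP / non-DP subset repertoires in which the planted clusters'
#' frequency is multiplied by `enrichment` in DP (and the DP background
#' is less diverse, as in sorted reactive subsets), (c) a two-condition
#' replicate count matrix with `n_expanded` clonotypes expanded at
#' `expansion_log2fc` under negative binomial noise, and (d) a small
#' specificity database matching half of each planted cluster, plus a
#' truth table of every planted effect.
#'
#' @param model a `recomb_model`.
#' @param design named list overriding entries of the default design
#'   (see the vignette for the stated world behind the defaults).
#' @param seed master seed; all randomness derives from it.
#' @return an object of class `tcr_study`: list(repertoires, counts,
#'   db, truth, patient_hla, design, seed).
#' @export
generate_study <- function(model, design = list(), seed = 1L) {
  des <- utils::modifyList(default_study_design(), design)
  base <- generate_null_repertoire(model, des$n_clonotypes,
                                   seed = derive_seed(seed, "base"),
                                   sample_id = "bulk")
  planted <- list()
  bulk <- base
  for (k in seq_len(des$n_clusters)) {
    pl <- plant_convergent_cluster(bulk, model,
                                   cluster_size = des$cluster_size,
                                   target_freq = des$cluster_freq,
                                   seed = derive_seed(seed,
                                                      paste0("plant", k)))
    bulk <- pl$repertoire
    tr <- pl$truth
    tr[, antigen := PLANTED_ANTIGENS$antigen[
      (k - 1L) %% nrow(PLANTED_ANTIGENS) + 1L]]
    planted[[k]] <- tr
  }
  truth_planted <- data.table::rbindlist(planted)
  truth_planted[, key := clonotype_key(cdr3aa, v, j)]
  bulk$metadata <- list(subset = "FFT")

  # ---- sorted subsets ------------------------------------------------
  bg <- bulk$clonotypes[!clonotype_key(cdr3aa, v, j) %in%
                          truth_planted$key]
  data.table::setorder(bg, -count, cdr3aa)
  pl_rows <- bulk$clonotypes[clonotype_key(cdr3aa, v, j) %in%
                               truth_planted$key]
  make_freqs <- function(n_bg, planted_scale) {
    b <- bg[seq_len(min(n_bg, nrow(bg)))]
    p <- data.table::copy(pl_rows)
    pl_tot <- min(0.9, planted_scale * des$n_clusters * des$cluster_freq)
    p[, freq := pl_tot * freq / sum(freq)]
    b[, freq := (1 - pl_tot) * count / sum(count)]
    data.table::rbindlist(list(b, p))[, .(cdr3nt, cdr3aa, v, d, j, freq)]
  }
  dp <- with_seed(derive_seed(seed, "dp"),
                  sample_subset(make_freqs(des$n_dp_background,
                                           des$enrichment),
                                truth_planted$key, des$subset_reads, "DP",
                                list(subset = "DP")))
  nondp <- with_seed(derive_seed(seed, "nondp"),
                     sample_subset(make_freqs(des$n_nondp_background, 1),
                                   truth_planted$key, des$subset_reads,
                                   "nonDP", list(subset = "non-DP")))

  # ---- replicate count matrix ---------------------------------------
  cm <- with_seed(derive_seed(seed, "counts"), {
    rows <- data.table::copy(bulk$clonotypes)
    data.table::setorder(rows, -freq, cdr3aa)
    rows <- rows[seq_len(min(des$n_counted, nrow(rows)))]
    rows[, key := clonotype_key(cdr3aa, v, j)]
    mu0 <- rows$freq / sum(rows$freq) * des$replicate_reads
    eligible_planted <- which(rows$key %in% truth_planted$key & mu0 >= 3)
    eligible_bg <- which(!rows$key %in% truth_planted$key & mu0 >= 3)
    n_pl <- min(length(eligible_planted), floor(des$n_expanded / 2))
    exp_idx <- c(eligible_planted[seq_len(n_pl)],
                 eligible_bg[sample.int(length(eligible_bg),
                                        des$n_expanded - n_pl)])
    fc <- rep(1, nrow(rows))
    fc[exp_idx] <- 2^des$expansion_log2fc
    smp <- as.vector(t(outer(des$conditions,
                             seq_len(des$n_replicates), paste, sep = "_")))
    cond <- rep(des$conditions, each = des$n_replicates)
    counts <- matrix(0L, nrow(rows), length(smp),
                     dimnames = list(rows$key, smp))
    for (jcol in seq_along(smp)) {
      mu <- if (cond[jcol] == des$focal_condition) mu0 * fc else mu0
      counts[, jcol] <- stats::rnbinom(nrow(rows), mu = mu,
                                       size = 1 / des$dispersion)
    }
    list(m = count_matrix(counts, cond),
         expanded = data.table::as.data.table(list(
           key = rows$key[exp_idx],
           true_log2fc = des$expansion_log2fc)))
  })

  # ---- specificity database -----------------------------------------
  db <- truth_planted[, {
    n_match <- ceiling(.N / 2)
    ann <- PLANTED_ANTIGENS[PLANTED_ANTIGENS$antigen == antigen[1L], ]
    .(cdr3aa = cdr3aa[seq_len(n_match)], v = v[seq_len(n_match)],
      j = j[seq_len(n_match)], epitope = ann$epitope,
      antigen = ann$antigen, hla = ann$hla)
  }, by = cluster_id][, cluster_id := NULL]

  structure(list(
    repertoires = list(bulk = bulk, DP = dp, nonDP = nondp),
    counts = cm$m,
    db = db[],
    truth = list(planted = truth_planted[], expanded = cm$expanded),
    patient_hla = SYNTHETIC_PATIENT_HLA,
    design = des, seed = seed),
    class = "tcr_study")
}

#' @export
print.tcr_study <- function(x, ...) {
  cat(sprintf(paste0("<tcr_study> seed %s: %d repertoires, %d planted",
                     " clonotypes in %d clusters, %d expanded keys\n"),
              format(x$seed), length(x$repertoires),
              nrow(x$truth$planted),
              length(unique(x$truth$planted$cluster_id)),
              nrow(x$truth$expanded)))
  invisible(x)
}

#' Write a study to disk in plain-text formats
#'
#' One VDJtools-style TSV per repertoire, `counts.tsv` + `design.tsv`
#' for the replicate matrix, `specificity_db.tsv`, and `truth.json`
#' (planted clusters, expanded keys, patient HLA, design, seed).
#' Deterministic: the same study writes byte-identical files.
#'
#' @param study a `tcr_study`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, `out_dir`.
#' @export
write_study <- function(study, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir)) stop("cannot create ", out_dir)
  for (nm in names(study$repertoires))
    write_repertoire(study$repertoires[[nm]],
                     file.path(out_dir, paste0(nm, ".tsv")))
  write_count_matrix(study$counts, file.path(out_dir, "counts.tsv"),
                     file.path(out_dir, "design.tsv"))
  data.table::fwrite(study$db, file.path(out_dir, "specificity_db.tsv"),
                     sep = "\t")
  jsonlite::write_json(
    list(planted = study$truth$planted, expanded = study$truth$expanded,
         patient_hla = study$patient_hla, design = study$design,
         seed = study$seed),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

#' Generate and write the default paper-shaped study
#'
#' Convenience wrapper: [generate_study()] on the packaged human-like
#' model with the default design (bulk of ~3000 clonotypes, DP/non-DP
#' subsets with enrichment factor 10, 2 conditions x 6 replicates with
#' 20 clonotypes expanded at log2 fold-change 3), written via
#' [write_study()].
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param model optional `recomb_model` (default: packaged human-like).
#' @return the `tcr_study`, invisibly.
#' @export
make_paper_shaped_study <- function(seed, out_dir,
                                    model = example_model("human")) {
  study <- generate_study(model, seed = seed)
  write_study(study, out_dir)
  invisible(study)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir study directory.
#' @return a `tcr_study` (truth restored from `truth.json`).
#' @export
read_study <- function(dir) {
  reps <- list()
  for (f in sort(list.files(dir, pattern = "\\.tsv$"))) {
    nm <- sub("\\.tsv$", "", f)
    if (nm %in% c("counts", "design", "specificity_db")) next
    reps[[nm]] <- read_repertoire(file.path(dir, f))
  }
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(
    repertoires = reps,
    counts = read_count_matrix(file.path(dir, "counts.tsv"),
                               file.path(dir, "design.tsv")),
    db = read_specificity_db(file.path(dir, "specificity_db.tsv")),
    truth = list(planted = data.table::as.data.table(truth$planted),
                 expanded = data.table::as.data.table(truth$expanded)),
    patient_hla = truth$patient_hla,
    design = truth$design, seed = truth$seed),
    class = "tcr_study")
}
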
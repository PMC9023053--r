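# cli_pipeline: chained prep -> alice -> cluster -> annotate -> stats
# -> expand run with a config, per-stage outputs, and a manifest.

#' Build a validated pipeline configuration
#'
#' Every analysis parameter carries its published default (alpha 0.001,
#' n_sim 5e6, n_batches 20, FDR 0.01, log2FC 1, singleton removal on);
#' the defaults are all serialized into the run manifest.
#'
#' @param samples named character vector of repertoire TSV paths.
#' @param model_path path to a recombination-model JSON file.
#' @param out_dir output directory.
#' @param db_path optional specificity-database TSV.
#' @param patient_hla optional character vector of patient HLA alleles.
#' @param counts_path,design_path optional replicate count matrix and
#'   design TSVs for the expansion stage.
#' @param focal_condition condition whose expansion is called.
#' @param dp_sample,nondp_sample optional names (in `samples`) of the
#'   sorted subsets used for expansion-call matching.
#' @param alpha,n_sim,n_batches,q_factor neighbor-test parameters.
#' @param central_lo,central_hi,majority_threshold annotation
#'   parameters.
#' @param fdr,lfc expansion calling thresholds.
#' @param min_size minimum cluster size.
#' @param node_set `"hits_neighbors"` (hit nuclei plus their
#'   Hamming-1 neighborhood) or `"all"` (whole repertoire graph).
#' @param remove_singletons,downsample_to pre-processing switches.
#' @param top_n rank cutoff for subset matching (default 1500).
#' @param seed master seed; each stage derives its own sub-seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(samples, model_path, out_dir,
                            db_path = NULL, patient_hla = NULL,
                            counts_path = NULL, design_path = NULL,
                            focal_condition = NULL,
                            dp_sample = NULL, nondp_sample = NULL,
                            alpha = 0.001, n_sim = 5e6, n_batches = 20,
                            q_factor = 1.0, central_lo = 4L,
                            central_hi = 3L, majority_threshold = 0.5,
                            fdr = 0.01, lfc = 1.0, min_size = 2L,
                            node_set = c("hits_neighbors", "all"),
                            remove_singletons = TRUE,
                            downsample_to = NULL, top_n = 1500L,
                            seed = 1L) {
  cfg <- list(samples = samples, model_path = model_path,
              out_dir = out_dir, db_path = db_path,
              patient_hla = patient_hla, counts_path = counts_path,
              design_path = design_path,
              focal_condition = focal_condition,
              dp_sample = dp_sample, nondp_sample = nondp_sample,
              alpha = alpha, n_sim = n_sim, n_batches = n_batches,
              q_factor = q_factor, central_lo = central_lo,
              central_hi = central_hi,
              majority_threshold = majority_threshold, fdr = fdr,
              lfc = lfc, min_size = min_size,
              node_set = match.arg(node_set),
              remove_singletons = remove_singletons,
              downsample_to = downsample_to, top_n = top_n, seed = seed)
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$model_path) || !file.exists(cfg$model_path))
    stop("config: model_path missing or not found")
  if (!length(cfg$samples)) stop("config: no samples")
  if (is.null(names(cfg$samples)) || any(!nzchar(names(cfg$samples))))
    stop("config: samples must be a named vector")
  for (p in cfg$samples)
    if (!file.exists(p)) stop("config: sample file not found: ", p)
  if (!is.null(cfg$db_path) && !file.exists(cfg$db_path))
    stop("config: db_path not found: ", cfg$db_path)
  if (xor(is.null(cfg$counts_path), is.null(cfg$design_path)))
    stop("config: counts_path and design_path must be given together")
  if (!is.null(cfg$counts_path) && is.null(cfg$focal_condition))
    stop("config: focal_condition required with counts")
  invisible(cfg)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full convergence-analysis pipeline
#'
#' Executes prep (optional singleton removal / down-sampling), the
#' neighbor-enrichment test, cluster construction with GML export,
#' specificity annotation with cluster-level propagation, diversity
#' statistics, and (when a count matrix is configured) the expansion
#' test. Writes per-stage TSVs, a `summary.tsv`, and `manifest.json`
#' into `out_dir`. Fully deterministic given the config (per-stage
#' seeds are derived from the master seed by stage name).
#'
#' @param config a `pipeline_config` (or plain list with the same
#'   fields).
#' @return invisibly, a list with the summary table, per-sample
#'   results, cluster sets, labels, and expansion results.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- read_model(cfg$model_path)
  db <- if (!is.null(cfg$db_path)) read_specificity_db(cfg$db_path)
  cache <- new.env(parent = emptyenv())
  per_sample <- list()
  summary_rows <- list()
  for (nm in names(cfg$samples)) {
    stage_log("prep", "reading %s", cfg$samples[[nm]])
    rep <- read_repertoire(cfg$samples[[nm]], sample_id = nm)
    if (!is.null(cfg$downsample_to) &&
        cfg$downsample_to < total_reads(rep))
      rep <- downsample(rep, cfg$downsample_to,
                        seed = derive_seed(cfg$seed,
                                           paste0("downsample:", nm)))
    # run_alice applies singleton removal itself; honoring the switch
    # here only matters for the "off" setting of exploratory runs.
    stage_log("alice", "%s: %d clonotypes", nm, n_clonotypes(rep))
    res <- run_alice(rep, model, alpha = cfg$alpha, n_sim = cfg$n_sim,
                     n_batches = cfg$n_batches,
                     q_factor = cfg$q_factor,
                     seed = derive_seed(cfg$seed, "alice"),
                     cache = cache)
    data.table::fwrite(res, file.path(cfg$out_dir,
                                      paste0(nm, ".alice.tsv")),
                       sep = "\t")
    stage_log("cluster", "%s: %d hits", nm, sum(res$is_hit))
    nodes <- if (cfg$node_set == "all") {
      tab <- as_node_table(rep)
      tab[, hit := clonotype_key(cdr3aa, v, j) %in%
            clonotype_key(res$cdr3aa[res$is_hit], res$v[res$is_hit],
                          res$j[res$is_hit])]
      tab
    } else hits_with_neighbors(rep, res)
    cs <- extract_clusters(build_graph(nodes), min_size = cfg$min_size)
    export_gml(cs, file.path(cfg$out_dir, paste0(nm, ".gml")))
    labels <- NULL
    taa_bulk <- taa_cluster <- NA_real_
    if (!is.null(db) && nrow(cs$clusters)) {
      stage_log("annotate", "%s: %d clusters", nm,
                length(unique(cs$clusters$cluster_id)))
      matches <- match_clonotypes(cs$clusters, db,
                                  patient_hla = cfg$patient_hla,
                                  central_lo = cfg$central_lo,
                                  central_hi = cfg$central_hi)
      labels <- annotate_clusters(cs, matches,
                                  cfg$majority_threshold)
      lab_members <- cs$clusters[labels, on = "cluster_id"]
      lab_keys <- lab_members[specificity != "unassigned",
                              clonotype_key(cdr3aa, v, j)]
      # bulk scope additionally counts direct database matches
      # outside clusters
      direct <- match_clonotypes(rep, db,
                                 patient_hla = cfg$patient_hla,
                                 central_lo = cfg$central_lo,
                                 central_hi = cfg$central_hi)
      bulk_keys <- union(lab_keys,
                         direct[, clonotype_key(cdr3aa, v, j)])
      cl_keys <- cs$clusters[, clonotype_key(cdr3aa, v, j)]
      taa_bulk <- cumulative_specific_frequency(rep, bulk_keys,
                                                scope = "bulk")
      taa_cluster <- cumulative_specific_frequency(
        rep, bulk_keys, scope = "cluster_related",
        cluster_keys = cl_keys)
      data.table::fwrite(
        lab_members[, .(cluster_id, cdr3aa, v, j, freq, sample,
                        specificity)],
        file.path(cfg$out_dir, paste0(nm, ".clusters.tsv")), sep = "\t")
    } else if (nrow(cs$clusters)) {
      data.table::fwrite(cs$clusters,
                         file.path(cfg$out_dir,
                                   paste0(nm, ".clusters.tsv")),
                         sep = "\t")
    }
    div <- clonality(rep)
    per_sample[[nm]] <- list(repertoire = rep, alice = res,
                             clusters = cs, labels = labels)
    summary_rows[[nm]] <- data.table::data.table(
      sample = nm,
      n_input = attr(res, "n_input"),
      n_tested = attr(res, "n_tested"),
      n_hits = sum(res$is_hit),
      normalized_hits = normalized_hits(res),
      n_clusters = length(unique(cs$clusters$cluster_id)),
      total_cluster_weight = sum(cs$weights$weight),
      taa_bulk_freq = taa_bulk,
      taa_cluster_freq = taa_cluster,
      clonality = div$clonality)
  }
  summary <- data.table::rbindlist(summary_rows)

  expansion <- NULL
  if (!is.null(cfg$counts_path)) {
    stage_log("expand", "testing %s vs reference", cfg$focal_condition)
    cm <- read_count_matrix(cfg$counts_path, cfg$design_path)
    expansion <- nb_exact_test(cm, focal = cfg$focal_condition,
                               fdr = cfg$fdr, lfc = cfg$lfc)
    data.table::fwrite(expansion,
                       file.path(cfg$out_dir, "expansion.tsv"),
                       sep = "\t")
    called <- call_expanded(expansion, cfg$fdr, cfg$lfc)
    exp_sum <- data.table::data.table(n_called = length(called))
    for (sub in c(cfg$dp_sample, cfg$nondp_sample)) {
      if (is.null(sub) || !sub %in% names(per_sample)) next
      refrep <- per_sample[[sub]]$repertoire
      exp_sum[, paste0("matched_", sub) :=
                subset_match_count(called, refrep)]
      exp_sum[, paste0("matched_top", cfg$top_n, "_", sub) :=
                subset_match_count(called, refrep, top_n = cfg$top_n)]
    }
    data.table::fwrite(exp_sum,
                       file.path(cfg$out_dir, "expansion_summary.tsv"),
                       sep = "\t")
  }
  data.table::fwrite(summary, file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t")
  manifest <- list(
    package = "tcrconv",
    version = as.character(utils::packageVersion("tcrconv")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    config_hash = digest_config(cfg))
  jsonlite::write_json(manifest, file.path(cfg$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, samples = per_sample,
                 expansion = expansion))
}

# Small order-stable config fingerprint (no external digest dependency).
digest_config <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                        digits = NA, null = "null")
  x <- utf8ToInt(s)
  h1 <- 0; h2 <- 0
  for (ch in x) {
    h1 <- (h1 * 31 + ch) %% 2147483647
    h2 <- (h2 * 131 + ch) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}
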
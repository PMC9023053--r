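# annotation: matching clonotypes to a VDJdb-style specificity database
# and propagating antigen labels to whole clusters.
#
# A database record matches a query clonotype iff
#   (1) the CDR3 amino-acid sequences are identical, OR differ at
#       exactly one *central* position (4..L-3, 1-based by default)
#       where both residues belong to the same physicochemical group;
#   (2) when the patient's HLA alleles are known, the record's HLA
#       restriction matches one of them.
# V/J gene equality is reported as a quality flag but never required.

# Physicochemical groups (R-property groups). The group names are
# standard; the exact membership is a package choice, declared here and
# overridable via the `groups` argument of aa_group().
AA_GROUP_TABLE <- c(
  G = "aliphatic", A = "aliphatic", V = "aliphatic", L = "aliphatic",
  I = "aliphatic", P = "aliphatic", M = "aliphatic",
  F = "aromatic", W = "aromatic", Y = "aromatic",
  S = "polar", T = "polar", C = "polar", N = "polar", Q = "polar",
  K = "positive", R = "positive", H = "positive",
  D = "negative", E = "negative")

#' Physicochemical group of an amino-acid residue
#'
#' @param residue character vector of single-letter residues.
#' @param groups named character vector residue -> group label;
#'   defaults to the package table (aliphatic GAVLIPM, aromatic FWY,
#'   polar STCNQ, positive KRH, negative DE).
#' @return group labels.
#' @export
aa_group <- function(residue, groups = AA_GROUP_TABLE) {
  out <- groups[residue]
  if (anyNA(out))
    stop("non-standard amino-acid letter: ",
         paste(unique(residue[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Read a specificity database table
#'
#' Tab-separated with columns `cdr3aa`, `v`, `j`, `epitope`, `antigen`,
#' `hla` (a VDJdb-export-compatible column subset).
#'
#' @param path TSV path.
#' @return a data.table of specificity records.
#' @export
read_specificity_db <- function(path) {
  db <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  names(db) <- tolower(names(db))
  need <- c("cdr3aa", "v", "j", "epitope", "antigen", "hla")
  miss <- setdiff(need, names(db))
  if (length(miss))
    stop("specificity database missing column(s): ",
         paste(miss, collapse = ", "))
  db[, need, with = FALSE]
}

# Does each db allele match any patient allele? Gene-level records
# ("A*02") match any patient allele of that allele group; four-digit
# records ("A*02:01") require four-digit equality.
hla_matches <- function(db_hla, patient_hla) {
  pat <- trimws(patient_hla)
  pat2 <- sub("^([^:]*:[^:]*).*$", "\\1", pat)   # first two fields
  patg <- sub(":.*$", "", pat)                   # gene*group
  vapply(db_hla, function(a) {
    a <- trimws(a)
    if (!nzchar(a)) return(FALSE)
    if (grepl(":", a, fixed = TRUE)) {
      a2 <- sub("^([^:]*:[^:]*).*$", "\\1", a)
      a2 %in% pat2
    } else {
      a %in% patg
    }
  }, NA, USE.NAMES = FALSE)
}

#' Match clonotypes against a specificity database
#'
#' Applies the three matching rules (CDR3 identity or one central
#' within-group substitution; optional HLA restriction; V/J reported
#' but not required). Positions `central_lo .. L - central_hi` (1-based)
#' count as central.
#'
#' @param queries a `tcr_repertoire` or data.frame with columns
#'   `cdr3aa`, `v`, `j`.
#' @param db specificity records (see [read_specificity_db()]).
#' @param patient_hla optional character vector of patient alleles
#'   ("A*02:01"-style); when given, records failing the HLA rule are
#'   dropped unless `require_hla = FALSE`.
#' @param central_lo first central position (default 4).
#' @param central_hi positions trimmed from the C-terminus (default 3,
#'   i.e. last central position is `L - 3`).
#' @param require_hla drop matches with `hla_pass == FALSE`.
#' @param groups residue-group table, see [aa_group()].
#' @return data.table(cdr3aa, v, j, db_cdr3aa, db_v, db_j, epitope,
#'   antigen, hla, match_type, mismatch_pos, hla_pass, vj_match).
#' @export
match_clonotypes <- function(queries, db, patient_hla = NULL,
                             central_lo = 4L, central_hi = 3L,
                             require_hla = TRUE,
                             groups = AA_GROUP_TABLE) {
  q <- if (inherits(queries, "tcr_repertoire"))
    queries$clonotypes[, .(cdr3aa, v, j)]
  else data.table::as.data.table(queries)[, .(cdr3aa, v, j)]
  q <- unique(q)
  db <- data.table::as.data.table(db)
  if (!nrow(db)) stop("empty specificity database")
  db <- data.table::copy(db)
  db[, hla_pass := if (is.null(patient_hla)) TRUE
     else hla_matches(hla, patient_hla)]
  out <- vector("list", nrow(q))
  db[, len := nchar(cdr3aa)]
  for (i in seq_len(nrow(q))) {
    qa <- q$cdr3aa[i]
    L <- nchar(qa)
    cand <- db[len == L]
    if (!nrow(cand)) next
    mm <- mismatch_count(cand$cdr3aa, qa)
    keep_exact <- mm == 0L
    keep_sub <- rep(FALSE, nrow(cand))
    pos1 <- rep(NA_integer_, nrow(cand))
    one <- which(mm == 1L)
    if (length(one) && central_lo <= L - central_hi) {
      for (k in one) {
        p <- which(strsplit(cand$cdr3aa[k], "")[[1]] !=
                     strsplit(qa, "")[[1]])
        if (p >= central_lo && p <= L - central_hi &&
            groups[substr(qa, p, p)] == groups[substr(cand$cdr3aa[k],
                                                      p, p)]) {
          keep_sub[k] <- TRUE
          pos1[k] <- p
        }
      }
    }
    sel <- keep_exact | keep_sub
    if (!any(sel)) next
    hit <- cand[sel]
    res <- data.table::data.table(
      cdr3aa = qa, v = q$v[i], j = q$j[i],
      db_cdr3aa = hit$cdr3aa, db_v = hit$v, db_j = hit$j,
      epitope = hit$epitope, antigen = hit$antigen, hla = hit$hla,
      match_type = ifelse(keep_exact[sel], "exact",
                          "central_substitution"),
      mismatch_pos = pos1[sel],
      hla_pass = hit$hla_pass,
      vj_match = strip_allele(hit$v) == strip_allele(q$v[i]) &
        strip_allele(hit$j) == strip_allele(q$j[i]))
    out[[i]] <- res
  }
  res <- data.table::rbindlist(out)
  if (!nrow(res))
    return(data.table::data.table(
      cdr3aa = character(), v = character(), j = character(),
      db_cdr3aa = character(), db_v = character(), db_j = character(),
      epitope = character(), antigen = character(), hla = character(),
      match_type = character(), mismatch_pos = integer(),
      hla_pass = logical(), vj_match = logical()))
  if (!is.null(patient_hla) && require_hla) res <- res[hla_pass == TRUE]
  res[]
}

#' Propagate a specificity label to a whole cluster
#'
#' If more than `majority_threshold` of the *matched* members share one
#' antigen label and no other antigen ties it, the cluster receives
#' that label and every member (matched or not) inherits it; otherwise
#' the cluster is `"unassigned"`. With no matched member the cluster is
#' `"unassigned"`.
#'
#' @param cluster_members data.frame with columns `cdr3aa`, `v`, `j`
#'   (one cluster's members).
#' @param matches output of [match_clonotypes()] covering the members.
#' @param majority_threshold strict majority fraction (default 0.5).
#' @return the cluster's antigen label (character scalar).
#' @export
propagate_cluster_specificity <- function(cluster_members, matches,
                                          majority_threshold = 0.5) {
  mem <- data.table::as.data.table(cluster_members)
  mkey <- unique(clonotype_key(mem$cdr3aa, mem$v, mem$j))
  rel <- matches[clonotype_key(cdr3aa, v, j) %in% mkey]
  if (!nrow(rel)) return("unassigned")
  per_member <- unique(rel[, .(key = clonotype_key(cdr3aa, v, j),
                               antigen)])
  tab <- per_member[, .(n = length(unique(key))), by = antigen]
  n_matched <- length(unique(per_member$key))
  data.table::setorder(tab, -n, antigen)
  if (tab$n[1L] <= majority_threshold * n_matched) return("unassigned")
  if (nrow(tab) > 1L && tab$n[2L] == tab$n[1L]) return("unassigned")
  tab$antigen[1L]
}

#' Label all clusters of a cluster set
#'
#' Convenience wrapper applying [propagate_cluster_specificity()] to
#' every cluster.
#'
#' @param cs a `cluster_set` with clusters extracted.
#' @param matches output of [match_clonotypes()].
#' @param majority_threshold see [propagate_cluster_specificity()].
#' @return data.table(cluster_id, specificity).
#' @export
annotate_clusters <- function(cs, matches, majority_threshold = 0.5) {
  if (is.null(cs$clusters)) stop("extract clusters first")
  cs$clusters[, .(specificity = propagate_cluster_specificity(
    .SD, matches, majority_threshold)), by = cluster_id]
}

#' Cumulative frequency of labeled clonotypes
#'
#' `scope = "bulk"`: summed frequency of all labeled clonotypes in the
#' repertoire. `scope = "cluster_related"`: the sum restricted to
#' cluster members, still expressed as a proportion of the whole
#' repertoire, so the cluster-related value can never exceed the bulk
#' value.
#'
#' @param rep a `tcr_repertoire`.
#' @param labeled_keys character vector of clonotype keys
#'   (`cdr3aa|V|J`, see [repertoire_keys()]) carrying the label of
#'   interest.
#' @param scope `"bulk"` or `"cluster_related"`.
#' @param cluster_keys keys of all cluster members (required for
#'   `scope = "cluster_related"`).
#' @return a fraction of the whole repertoire.
#' @export
cumulative_specific_frequency <- function(rep, labeled_keys,
                                          scope = c("bulk",
                                                    "cluster_related"),
                                          cluster_keys = NULL) {
  scope <- match.arg(scope)
  rk <- repertoire_keys(rep)
  sel <- rk %in% labeled_keys
  if (scope == "cluster_related") {
    if (is.null(cluster_keys))
      stop("cluster_keys required for scope = 'cluster_related'")
    sel <- sel & rk %in% cluster_keys
  }
  sum(rep$clonotypes$freq[sel])
}
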
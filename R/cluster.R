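# cluster_graph: CDR3 similarity graphs, connected-component clusters,
# cluster weights, GML export.
#
# Edge rule (deliberately looser than the neighbor test): two nodes are
# connected iff their CDR3 amino-acid sequences have equal length and
# Hamming distance <= 1. V/J identity is NOT required, so two nodes
# carrying the same CDR3 with different V genes are joined by a
# distance-0 edge. In composite graphs, identical clonotypes from
# different samples are kept as separate nodes.

node_id <- function(sample, cdr3aa, v, j) {
  paste(sample, cdr3aa, v, j, sep = "|")
}

# Normalize assorted inputs into a node table.
as_node_table <- function(x, sample_id = NULL) {
  if (inherits(x, "tcr_repertoire")) {
    dt <- data.table::copy(x$clonotypes[, .(cdr3aa, v, j, freq)])
    dt[, sample := sample_id %||% x$sample_id]
    return(dt)
  }
  dt <- data.table::as.data.table(x)
  if (!all(c("cdr3aa", "v", "j") %in% names(dt)))
    stop("node table needs columns cdr3aa, v, j")
  if (!"freq" %in% names(dt)) dt[, freq := NA_real_]
  if (!"sample" %in% names(dt))
    dt[, sample := sample_id %||% "sample"]
  dt[, .(cdr3aa, v, j, freq, sample)]
}

#' Build a CDR3 similarity graph
#'
#' Nodes are clonotypes (optionally tagged with extra attributes);
#' edges join nodes whose CDR3 amino-acid sequences have equal length
#' and Hamming distance at most 1 (V/J equality not required).
#'
#' @param clonotypes a `tcr_repertoire` or a data.frame with columns
#'   `cdr3aa`, `v`, `j` and optionally `freq`, `sample`, `hit`,
#'   `specificity`.
#' @param edge_rule only `"hamming1"` is defined.
#' @return an object of class `cluster_set`: list with an `igraph`
#'   graph and the node table.
#' @export
build_graph <- function(clonotypes, edge_rule = c("hamming1")) {
  edge_rule <- match.arg(edge_rule)
  nodes <- as_node_table(clonotypes)
  if (is.data.frame(clonotypes)) {
    src <- data.table::as.data.table(clonotypes)
    for (cc in intersect(c("hit", "specificity"), names(src)))
      nodes[, (cc) := src[[cc]]]
  }
  if (any(!nzchar(nodes$cdr3aa))) stop("empty CDR3 in node table")
  nodes[, id := node_id(sample, cdr3aa, v, j)]
  if (anyDuplicated(nodes$id)) stop("duplicated graph nodes")
  data.table::setorder(nodes, id)
  nodes[, row := .I]
  edges <- data.table::data.table(from = integer(), to = integer())
  nodes[, len := nchar(cdr3aa)]
  for (L in unique(nodes$len)) {
    sub <- nodes[len == L]
    if (nrow(sub) < 2L) next
    mt <- masked_table(sub$cdr3aa)
    mt[, row := sub$row[idx]]
    pairs <- mt[mt, on = c("pos", "masked"), allow.cartesian = TRUE,
                .(from = x.row, to = i.row)][from < to]
    edges <- rbind(edges, unique(pairs))
  }
  edges <- unique(edges)
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes$id)
  g <- igraph::set_vertex_attr(g, "label", value = nodes$cdr3aa)
  g <- igraph::set_vertex_attr(g, "freq",
                               value = ifelse(is.na(nodes$freq), 0,
                                              nodes$freq))
  g <- igraph::set_vertex_attr(g, "sample", value = nodes$sample)
  if ("hit" %in% names(nodes))
    g <- igraph::set_vertex_attr(g, "hit", value = as.integer(nodes$hit))
  if ("specificity" %in% names(nodes))
    g <- igraph::set_vertex_attr(g, "specificity",
                                 value = nodes$specificity)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  nodes[, `:=`(row = NULL, len = NULL)]
  structure(list(graph = g, nodes = nodes, clusters = NULL,
                 weights = NULL),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d nodes, %d edges",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  if (!is.null(x$clusters))
    cat(sprintf(", %d clusters (size >= %d)",
                length(unique(x$clusters$cluster_id)),
                attr(x$clusters, "min_size")))
  cat("\n")
  invisible(x)
}

#' Extract similarity clusters as connected components
#'
#' Computes connected components of the similarity graph and keeps
#' those with at least `min_size` nodes (isolated nodes are not
#' clusters). Cluster ids are the lexicographically smallest member
#' node id, so they are stable across runs and node orderings.
#'
#' @param cs a `cluster_set` from [build_graph()].
#' @param min_size minimum component size to retain (default 2).
#' @return the `cluster_set` with `clusters`
#'   (data.table(cluster_id, id, cdr3aa, v, j, freq, sample)) and
#'   `weights` (data.table(cluster_id, weight)) filled in.
#' @export
extract_clusters <- function(cs, min_size = 2L) {
  cmp <- igraph::components(cs$graph)
  memb <- data.table::data.table(id = igraph::V(cs$graph)$name,
                                 comp = cmp$membership)
  memb <- memb[comp %in% which(cmp$csize >= min_size)]
  if (nrow(memb)) memb[, cluster_id := min(id), by = comp]
  else memb[, cluster_id := character(0)]
  cl <- memb[cs$nodes, on = "id", nomatch = 0L,
             .(cluster_id, id, cdr3aa, v, j, freq, sample)]
  data.table::setorder(cl, cluster_id, id)
  data.table::setattr(cl, "min_size", min_size)
  w <- cl[, .(weight = sum(ifelse(is.na(freq), 0, freq))),
          by = cluster_id]
  data.table::setorder(w, cluster_id)
  cs$clusters <- cl
  cs$weights <- w
  cs
}

#' Cumulative frequency of a cluster within a repertoire
#'
#' @param cluster_members data.table/data.frame with columns `cdr3aa`,
#'   `v`, `j` (e.g. one cluster's rows from [extract_clusters()]).
#' @param rep the `tcr_repertoire` providing frequencies.
#' @return the sum of member frequencies in `rep`.
#' @export
cluster_weight <- function(cluster_members, rep) {
  mem <- data.table::as.data.table(cluster_members)
  keys <- unique(clonotype_key(mem$cdr3aa, mem$v, mem$j))
  rk <- repertoire_keys(rep)
  missing <- setdiff(keys, rk)
  if (length(missing))
    stop("cluster member absent from repertoire: ", missing[1L])
  sum(rep$clonotypes$freq[rk %in% keys])
}

#' Build a composite multi-sample similarity graph
#'
#' Identical clonotypes from different repertoires are displayed as
#' separate nodes; edges follow the same length-equal Hamming-at-most-1
#' rule across all nodes, so cross-sample copies of one clonotype are
#' joined by distance-0 edges.
#'
#' @param reps list of `tcr_repertoire` objects.
#' @param node_sets optional list (same length) of data.frames with
#'   columns `cdr3aa`, `v`, `j` restricting each repertoire's nodes;
#'   `NULL` entries keep all clonotypes.
#' @return a `cluster_set`.
#' @export
build_composite_graph <- function(reps, node_sets = NULL) {
  if (inherits(reps, "tcr_repertoire")) reps <- list(reps)
  tabs <- lapply(seq_along(reps), function(i) {
    tab <- as_node_table(reps[[i]])
    if (!is.null(node_sets) && !is.null(node_sets[[i]])) {
      keep <- data.table::as.data.table(node_sets[[i]])
      sel <- clonotype_key(tab$cdr3aa, tab$v, tab$j) %in%
        clonotype_key(keep$cdr3aa, keep$v, keep$j)
      if (!all(clonotype_key(keep$cdr3aa, keep$v, keep$j) %in%
                 clonotype_key(tab$cdr3aa, tab$v, tab$j)))
        stop("node set ", i, " contains keys absent from its repertoire")
      tab <- tab[sel]
    }
    tab
  })
  build_graph(data.table::rbindlist(tabs))
}

#' Default cluster node set: hits plus their Hamming-1 neighborhood
#'
#' The neighbor-test hits act as cluster nuclei; the node set also
#' includes every repertoire clonotype whose CDR3 has equal length and
#' Hamming distance at most 1 to some hit (V/J not required), since
#' published cluster figures include such non-hit members.
#'
#' @param rep a `tcr_repertoire`.
#' @param results [run_alice()] output for that repertoire.
#' @return data.table of node rows (cdr3aa, v, j, freq, sample, hit).
#' @export
hits_with_neighbors <- function(rep, results) {
  hits <- results[is_hit == TRUE]
  tab <- as_node_table(rep)
  hit_key <- clonotype_key(hits$cdr3aa, hits$v, hits$j)
  tab[, hit := clonotype_key(cdr3aa, v, j) %in% hit_key]
  if (!nrow(hits)) return(tab[hit == TRUE])
  keep <- tab$hit
  tab[, len := nchar(cdr3aa)]
  for (L in unique(nchar(hits$cdr3aa))) {
    rows <- which(tab$len == L)
    if (!length(rows)) next
    hseq <- unique(hits$cdr3aa[nchar(hits$cdr3aa) == L])
    for (h in hseq)
      keep[rows] <- keep[rows] |
        (mismatch_count(tab$cdr3aa[rows], h) <= 1L)
  }
  tab[, len := NULL]
  tab[keep]
}

#' Export / import a similarity graph in GML format
#'
#' Writes standard GML with node attributes id, label (the CDR3),
#' freq, sample and, when present, hit and specificity. Node order is
#' fixed by the sorted node ids, so the file is byte-deterministic.
#'
#' @param cs a `cluster_set`.
#' @param path output file.
#' @return `export_gml` returns `path` invisibly; `import_gml` returns
#'   an `igraph` graph.
#' @export
export_gml <- function(cs, path) {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write ", path))
  on.exit(close(con))
  igraph::write_graph(cs$graph, con, format = "gml")
  invisible(path)
}

#' @rdname export_gml
#' @export
import_gml <- function(path) {
  igraph::read_graph(path, format = "gml")
}
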
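# cluster_graph: edge rule, components, weights, composite graphs, GML.

test_that("edge rule: equal length, Hamming <= 1, V/J ignored", {
  dt <- data.table::data.table(
    cdr3aa = c("CASSF", "CASTF", "CSARVGNQPQHF", "CASSGGMGQPQHF"),
    v = "TRBV1", j = "TRBJ1", freq = 0.25)
  cs <- build_graph(dt)
  ed <- igraph::as_edgelist(cs$graph)
  expect_equal(nrow(ed), 1L)     # only CASSF-CASTF
  endpoints <- cs$nodes[id %in% as.vector(ed), cdr3aa]
  expect_setequal(endpoints, c("CASSF", "CASTF"))
  # identical CDR3 with different V genes: two nodes, one edge
  dt2 <- data.table::data.table(cdr3aa = "CASSF",
                                v = c("TRBV1", "TRBV2"), j = "TRBJ1",
                                freq = 0.5)
  cs2 <- build_graph(dt2)
  expect_equal(igraph::vcount(cs2$graph), 2L)
  expect_equal(igraph::ecount(cs2$graph), 1L)
})

test_that("build_graph matches the all-pairs edge oracle", {
  for (s in 1:8) {
    dt <- unique(random_fixture(120, seed = 2000 + s),
                 by = "cdr3aa")[, .(cdr3aa, v, j, freq)]
    cs <- build_graph(dt)
    # map igraph edges back to row indices of the sorted node table
    ids <- cs$nodes$id
    ord <- match(node_order <- ids, ids)
    el <- igraph::as_edgelist(cs$graph)
    got <- cbind(match(el[, 1], ids), match(el[, 2], ids))
    got <- t(apply(got, 1L, sort))
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    want <- oracle_edges(cs$nodes$cdr3aa)
    expect_equal(unname(got), unname(want),
                 info = paste("fixture seed", s))
  }
})

test_that("extract_clusters drops small components and has stable ids", {
  dt <- data.table::data.table(
    cdr3aa = c("CASSF", "CASTF", "CASSG",        # one triangle-ish blob
               "CATTTTF", "CATTTTW",             # one pair
               "CAQQQQQF"),                      # isolated
    v = "TRBV1", j = "TRBJ1", freq = 1 / 6)
  cs <- extract_clusters(build_graph(dt))
  expect_equal(length(unique(cs$clusters$cluster_id)), 2L)
  expect_false("CAQQQQQF" %in% cs$clusters$cdr3aa)
  # ids survive node-order permutation
  set.seed(3)
  cs2 <- extract_clusters(build_graph(dt[sample(.N)]))
  expect_setequal(unique(cs2$clusters$cluster_id),
                  unique(cs$clusters$cluster_id))
  expect_equal(cs2$clusters[order(id)], cs$clusters[order(id)])
  # empty graph
  empty <- extract_clusters(build_graph(
    data.table::data.table(cdr3aa = character(), v = character(),
                           j = character(), freq = numeric())))
  expect_equal(nrow(empty$clusters), 0L)
})

test_that("cluster weights sum member frequencies", {
  rep <- mini_rep(c(10, 5, 5, 80), c("CASSF", "CASTF", "CASSG", "CAAAF"))
  members <- rep$clonotypes[1:3, .(cdr3aa, v, j)]
  expect_equal(cluster_weight(members, rep), 0.2)
  expect_equal(cluster_weight(rep$clonotypes[, .(cdr3aa, v, j)], rep), 1)
  w12 <- cluster_weight(rep$clonotypes[1:2, .(cdr3aa, v, j)], rep)
  w3 <- cluster_weight(rep$clonotypes[3, .(cdr3aa, v, j)], rep)
  expect_equal(w12 + w3, 0.2)
  expect_error(cluster_weight(data.frame(cdr3aa = "CXXXF", v = "TRBV1",
                                         j = "TRBJ1"), rep),
               "CXXXF")
})

test_that("composite graphs keep per-sample nodes distinct", {
  a <- mini_rep(c(4, 2), c("CASSF", "CATTF"), sample_id = "a")
  b <- mini_rep(c(6, 2), c("CASSF", "CAGGF"), sample_id = "b")
  cs <- build_composite_graph(list(a, b))
  expect_equal(igraph::vcount(cs$graph), 4L)
  # shared clonotype: distance-0 edge across samples
  shared <- cs$nodes[cdr3aa == "CASSF"]
  expect_equal(nrow(shared), 2L)
  expect_true(igraph::are_adjacent(cs$graph, shared$id[1], shared$id[2]))
  # composite of one sample equals the plain graph
  solo <- build_composite_graph(list(a))
  plain <- build_graph(a)
  expect_equal(igraph::vcount(solo$graph), igraph::vcount(plain$graph))
  expect_equal(igraph::ecount(solo$graph), igraph::ecount(plain$graph))
  # node sets restrict and validate
  cs3 <- build_composite_graph(list(a, b),
                               node_sets = list(
                                 data.frame(cdr3aa = "CASSF",
                                            v = "TRBV1", j = "TRBJ1"),
                                 NULL))
  expect_equal(igraph::vcount(cs3$graph), 3L)
  expect_error(build_composite_graph(
    list(a), node_sets = list(data.frame(cdr3aa = "CZZZF", v = "TRBV1",
                                         j = "TRBJ1"))),
    "absent")
})

test_that("GML export round-trips and handles empty graphs", {
  dt <- data.table::data.table(cdr3aa = c("CASSF", "CASTF"),
                               v = "TRBV1", j = "TRBJ1",
                               freq = c(0.6, 0.4))
  cs <- build_graph(dt)
  f <- withr::local_tempfile(fileext = ".gml")
  export_gml(cs, f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^  node$|^  node \\[$|node$", txt)), 2L)
  g <- import_gml(f)
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
  expect_setequal(igraph::V(g)$label, c("CASSF", "CASTF"))
  # deterministic bytes
  f2 <- withr::local_tempfile(fileext = ".gml")
  export_gml(build_graph(dt[2:1]), f2)
  expect_identical(readLines(f), readLines(f2))
  # empty graph is still valid GML
  fe <- withr::local_tempfile(fileext = ".gml")
  export_gml(build_graph(
    data.table::data.table(cdr3aa = character(), v = character(),
                           j = character(), freq = numeric())), fe)
  ge <- import_gml(fe)
  expect_equal(igraph::vcount(ge), 0L)
})

test_that("hits_with_neighbors collects hit nuclei plus their ball", {
  rep <- mini_rep(c(9, 3, 3, 7), c("CASSF", "CASTF", "CATTF", "CAAAAAF"))
  res <- data.table::data.table(cdr3aa = "CASSF", v = "TRBV1",
                                j = "TRBJ1", is_hit = TRUE)
  nodes <- hits_with_neighbors(rep, res)
  expect_setequal(nodes$cdr3aa, c("CASSF", "CASTF"))
  expect_equal(nodes[cdr3aa == "CASSF", hit], TRUE)
  expect_equal(nodes[cdr3aa == "CASTF", hit], FALSE)
})
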
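# generative_model: sampling, productivity filter, ball Pgen oracles,
# synthetic repertoires.

test_that("degenerate model emits its single sequence with probability 1", {
  m <- degenerate_model()
  draw <- sample_rearrangement(m, rng_seed = 1)
  expect_equal(draw$cdr3_aa, "CASFF")
  expect_equal(draw$cdr3_nt, "TGTGCCAGCTTTTTC")
  # determinism of the draw stream
  expect_identical(sample_rearrangement(m, rng_seed = 42),
                   sample_rearrangement(m, rng_seed = 42))
  est <- estimate_ball_pgen(m, "CASFF", "V1", "J1", n_sim = 200,
                            seed = 1)
  expect_equal(est$point, 1)
  expect_equal(est$std_error, 0)
  expect_equal(exact_ball_pgen(m, "CASFF", "V1", "J1"), 1)
})

test_that("out-of-frame insertions are rejected", {
  m <- recombination_model(
    v_segments = c("V1" = "TGTGCCAGC"),
    j_segments = c("J1" = "TTTTTC"),
    v_deletion_dist = 1, j_deletion_dist = 1,
    insertion_length_dist = c(0, 1),    # always 1 nt -> never in frame
    insertion_base_probs = c(A = 1, C = 0, G = 0, T = 0),
    vj_usage = data.frame(v = "V1", j = "J1", prob = 1))
  expect_null(sample_rearrangement(m, rng_seed = 3))
  ev <- enumerate_rearrangements(m, "V1", "J1")
  expect_false(any(ev$productive))
  expect_equal(sum(ev$prob), 1)
})

test_that("enumeration totals 1 and exact ball Pgen matches the hand oracle", {
  toy <- exact_toy_model()
  ev <- enumerate_rearrangements(toy, "TRBV-T", "TRBJ-T")
  expect_equal(sum(ev$prob), 1, tolerance = 1e-12)
  expect_equal(sum(ev$prob[ev$productive]), 0.8, tolerance = 1e-12)
  for (q in c("CASKFF", "CASSFF", "CASFF", "CASEFF")) {
    expect_equal(exact_ball_pgen(toy, q, "TRBV-T", "TRBJ-T"),
                 toy_ball_oracle(q), tolerance = 1e-12)
  }
  # unreachable length
  expect_equal(exact_ball_pgen(toy, "CASSSFF", "TRBV-T", "TRBJ-T"), 0)
  expect_equal(toy_ball_oracle("CASKFF"), 0.5)  # frozen hand value
})

test_that("Monte-Carlo ball Pgen agrees with enumeration within error", {
  toy <- exact_toy_model()
  est <- estimate_ball_pgen(toy, "CASSFF", "TRBV-T", "TRBJ-T",
                            n_sim = 20000, n_batches = 20, seed = 11)
  expect_lt(abs(est$point - 0.5), 4 * est$std_error + 1e-12)
  expect_gt(est$std_error, 0)
  # packaged toy fixture is the same model
  pk <- example_model("toy")
  expect_equal(exact_ball_pgen(pk, "CASSFF", "TRBV-T", "TRBJ-T"), 0.5)
  expect_error(estimate_ball_pgen(toy, "CASSFF", "TRBVX", "TRBJ-T",
                                  n_sim = 10, seed = 1),
               "absent")
})

test_that("enumeration refuses oversized models", {
  hm <- example_model("human")
  expect_error(enumerate_rearrangements(hm, "TRBV1", "TRBJ1-1"),
               "enumeration bound")
})

test_that("every productive draw satisfies the CDR3 convention", {
  hm <- example_model("human")
  rep <- generate_null_repertoire(hm, 400, seed = 21)
  aa <- rep$clonotypes$cdr3aa
  expect_true(all(startsWith(aa, "C")))
  expect_true(all(endsWith(aa, "F") | endsWith(aa, "W")))
  expect_false(any(grepl("*", aa, fixed = TRUE)))
  nt <- rep$clonotypes$cdr3nt
  expect_true(all(nchar(nt) %% 3 == 0))
})

test_that("generate_null_repertoire honors its contract", {
  hm <- example_model("human")
  rep <- generate_null_repertoire(hm, 150, seed = 5)
  expect_equal(n_clonotypes(rep), 150L)
  expect_false(anyDuplicated(repertoire_keys(rep)) > 0)
  expect_equal(sum(rep$clonotypes$freq), 1, tolerance = 1e-9)
  expect_true(all(rep$clonotypes$count >= 2L))
  rep2 <- generate_null_repertoire(hm, 150, seed = 5)
  expect_identical(rep$clonotypes, rep2$clonotypes)
  # capacity error on a model whose support is a single sequence
  expect_error(generate_null_repertoire(degenerate_model(), 10,
                                        seed = 1),
               "support")
})

test_that("geometric clone-size law has the right mean", {
  hm <- example_model("human")
  rep <- generate_null_repertoire(hm, 10000, seed = 8,
                                  count_law = "geometric",
                                  law_params = list(p = 0.5))
  counts <- rep$clonotypes$count
  # count = 2 + Geom(0.5): mean 3, var 2
  se <- sqrt(2 / length(counts))
  expect_lt(abs(mean(counts) - 3), 3 * se)
})

test_that("planted clusters are single-substitution stars at central positions", {
  hm <- example_model("human")
  base <- generate_null_repertoire(hm, 300, seed = 31)
  pl <- plant_convergent_cluster(base, hm, cluster_size = 5,
                                 target_freq = 0.1, seed = 17)
  tr <- pl$truth
  expect_equal(nrow(tr), 6L)   # seed + 5 variants
  seed_aa <- tr[role == "seed", cdr3aa]
  L <- nchar(seed_aa)
  for (vvar in tr[role == "variant", cdr3aa]) {
    dif <- which(strsplit(vvar, "")[[1]] != strsplit(seed_aa, "")[[1]])
    expect_length(dif, 1L)
    expect_gte(dif, 4L)
    expect_lte(dif, L - 3L)
  }
  # pairwise Hamming <= 2, same (V, J)
  combs <- utils::combn(tr$cdr3aa, 2)
  dd <- apply(combs, 2, function(x)
    sum(strsplit(x[1], "")[[1]] != strsplit(x[2], "")[[1]]))
  expect_true(all(dd <= 2))
  expect_equal(length(unique(tr$v)), 1L)
  # planted frequency mass is exact
  reps <- pl$repertoire
  pk <- clonotype_key(tr$cdr3aa, tr$v, tr$j)
  expect_equal(sum(reps$clonotypes$freq[repertoire_keys(reps) %in% pk]),
               0.1, tolerance = 1e-9)
  expect_equal(sum(reps$clonotypes$freq), 1, tolerance = 1e-9)
  # the planted set is one connected component of the similarity graph
  cs <- extract_clusters(build_graph(reps))
  memb <- cs$clusters[clonotype_key(cdr3aa, v, j) %in% pk]
  expect_equal(nrow(memb), 6L)
  expect_equal(length(unique(memb$cluster_id)), 1L)
  expect_error(plant_convergent_cluster(base, hm, cluster_size = 500,
                                        target_freq = 0.1, seed = 2),
               "central")
})
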
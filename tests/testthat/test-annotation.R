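# annotation: residue groups, three-rule matching, HLA filtering,
# cluster-level propagation, cumulative frequencies.

demo_db <- function() {
  data.table::data.table(
    cdr3aa = c("CSARVGNQPQHF", "CASSGGLGQPQHF", "CASSGGLGQPQHF",
               "CAWSVSDLAKNIQYF"),
    v = c("TRBV20", "TRBV19", "TRBV19", "TRBV30"),
    j = c("TRBJ1-5", "TRBJ1-5", "TRBJ1-5", "TRBJ2-4"),
    epitope = c("ELAGIGILTV", "ELAGIGILTV", "ELAGIGILTV", "SLLMWITQC"),
    antigen = c("Melan-A", "Melan-A", "Melan-A", "NY-ESO-1"),
    hla = c("A*02", "A*02:01", "B*08:01", "A*02:01"))
}

mp26_hla <- c("A*02:01", "A*26:01", "B*27:05", "B*73:01", "C*02:02",
              "C*15:05")

test_that("residue groups follow the fixed table", {
  expect_equal(aa_group(c("L", "M")), c("aliphatic", "aliphatic"))
  expect_equal(aa_group("D"), "negative")
  expect_equal(aa_group("K"), "positive")
  expect_equal(aa_group("F"), "aromatic")
  expect_equal(aa_group("S"), "polar")
  expect_error(aa_group("B"), "non-standard")
})

test_that("worked matching examples behave per the three rules", {
  db <- demo_db()
  # exact match of the printed clonotype, gene-level A*02 restriction
  # passes the patient allele list
  q <- data.frame(cdr3aa = "CSARVGNQPQHF", v = "TRBV20", j = "TRBJ1-5")
  m <- match_clonotypes(q, db, patient_hla = mp26_hla)
  expect_equal(nrow(m), 1L)
  expect_equal(m$match_type, "exact")
  expect_true(m$hla_pass)
  expect_true(m$vj_match)

  # central within-group substitution: M vs L at position 7 of 13
  q2 <- data.frame(cdr3aa = "CASSGGMGQPQHF", v = "TRBV19",
                   j = "TRBJ1-5")
  m2 <- match_clonotypes(q2, db, patient_hla = mp26_hla)
  expect_equal(unique(m2$match_type), "central_substitution")
  expect_equal(unique(m2$mismatch_pos), 7L)
  # the B*08:01-restricted copy is dropped by the HLA filter
  expect_equal(nrow(m2), 1L)
  m2b <- match_clonotypes(q2, db)   # no patient HLA: both retained
  expect_equal(nrow(m2b), 2L)

  # substitution at position 2: not central, no match
  q3 <- data.frame(cdr3aa = "CAARVGNQPQHF", v = "TRBV20",
                   j = "TRBJ1-5")
  expect_equal(nrow(match_clonotypes(q3, db)), 0L)

  # central but cross-group substitution (L -> D): no match
  q4 <- data.frame(cdr3aa = "CASSGGDGQPQHF", v = "TRBV19",
                   j = "TRBJ1-5")
  expect_equal(nrow(match_clonotypes(q4, db)), 0L)

  # two mismatches: no match
  q5 <- data.frame(cdr3aa = "CASSGGMGQPQHW", v = "TRBV19",
                   j = "TRBJ1-5")
  expect_equal(nrow(match_clonotypes(q5, db)), 0L)

  # V/J inequality is reported, not required
  q6 <- data.frame(cdr3aa = "CSARVGNQPQHF", v = "TRBV9", j = "TRBJ2-1")
  m6 <- match_clonotypes(q6, db)
  expect_equal(nrow(m6), 1L)
  expect_false(m6$vj_match)
})

test_that("HLA gene-level and four-digit records resolve correctly", {
  db <- demo_db()[1]
  db$hla <- "A*26"
  m <- match_clonotypes(data.frame(cdr3aa = "CSARVGNQPQHF",
                                   v = "TRBV20", j = "TRBJ1-5"),
                        db, patient_hla = mp26_hla)
  expect_equal(nrow(m), 1L)    # A*26 matches A*26:01
  db$hla <- "A*26:02"
  m2 <- match_clonotypes(data.frame(cdr3aa = "CSARVGNQPQHF",
                                    v = "TRBV20", j = "TRBJ1-5"),
                         db, patient_hla = mp26_hla)
  expect_equal(nrow(m2), 0L)   # four-digit mismatch
})

test_that("matcher equals the brute-force scan on random pairs", {
  set.seed(55)
  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
  rand_cdr3 <- function(n, lens = 9:13)
    vapply(sample(lens, n, replace = TRUE), function(L)
      paste(c("C", sample(aa[1:8], L - 2L, replace = TRUE), "F"),
            collapse = ""), "")
  db <- data.table::data.table(
    cdr3aa = rand_cdr3(100), v = sample(paste0("TRBV", 1:5), 100, TRUE),
    j = sample(paste0("TRBJ", 1:3), 100, TRUE),
    epitope = "PEP", antigen = sample(c("X", "Y"), 100, TRUE),
    hla = sample(c("A*02", "A*02:01", "B*07:02"), 100, TRUE))
  queries <- data.table::data.table(
    cdr3aa = c(rand_cdr3(80), db$cdr3aa[1:20]),
    v = "TRBV1", j = "TRBJ1")
  hla <- c("A*02:01", "B*07:02")
  m <- match_clonotypes(queries, db, patient_hla = hla)
  for (i in seq_len(nrow(queries))) {
    want <- sort(db$cdr3aa[oracle_match(queries$cdr3aa[i], db,
                                        patient_hla = hla)])
    got <- sort(m[cdr3aa == queries$cdr3aa[i] & v == "TRBV1",
                  db_cdr3aa])
    expect_equal(got, want, info = paste("query", i))
  }
})

test_that("cluster propagation follows the strict-majority rule", {
  members <- data.frame(
    cdr3aa = paste0("CASS", LETTERS[1:6], "QPQHF"),
    v = "TRBV19", j = "TRBJ1-5")
  mk_matches <- function(idx, antigen) data.table::data.table(
    cdr3aa = members$cdr3aa[idx], v = "TRBV19", j = "TRBJ1-5",
    db_cdr3aa = "x", db_v = "v", db_j = "j", epitope = "e",
    antigen = antigen, hla = "A*02", match_type = "exact",
    mismatch_pos = NA_integer_, hla_pass = TRUE, vj_match = TRUE)
  # 4 of 6 matched, all Melan-A: whole cluster inherits the label
  m <- mk_matches(1:4, "Melan-A")
  expect_equal(propagate_cluster_specificity(members, m), "Melan-A")
  # no matches
  expect_equal(propagate_cluster_specificity(members, m[0]),
               "unassigned")
  # 2 vs 2 tie
  tie <- rbind(mk_matches(1:2, "X"), mk_matches(3:4, "Y"))
  expect_equal(propagate_cluster_specificity(members, tie),
               "unassigned")
  # idempotent under member order
  expect_equal(propagate_cluster_specificity(members[6:1, ], m),
               "Melan-A")
  # 3 of 6 matched to one antigen is not a strict majority of... of
  # matched members it is (3/3); with one dissenting member (3 vs 1)
  # the majority holds
  mixed <- rbind(mk_matches(1:3, "Melan-A"), mk_matches(4, "Y"))
  expect_equal(propagate_cluster_specificity(members, mixed),
               "Melan-A")
})

test_that("cumulative specific frequency respects scope", {
  rep <- mini_rep(c(10, 20, 30, 40),
                  c("CASSF", "CASTF", "CAAAF", "CAAGF"))
  keys <- repertoire_keys(rep)
  expect_equal(cumulative_specific_frequency(rep, character(0)), 0)
  expect_equal(cumulative_specific_frequency(rep, keys), 1)
  lab <- keys[c(1, 3)]                     # freq .1 + .3
  cl <- keys[c(1, 2)]                      # cluster members
  expect_equal(cumulative_specific_frequency(rep, lab, "bulk"), 0.4)
  expect_equal(cumulative_specific_frequency(rep, lab,
                                             "cluster_related",
                                             cluster_keys = cl), 0.1)
  # cluster-related never exceeds bulk
  set.seed(10)
  for (i in 1:20) {
    lab_i <- sample(keys, sample(0:4, 1))
    cl_i <- sample(keys, sample(0:4, 1))
    expect_lte(cumulative_specific_frequency(rep, lab_i,
                                             "cluster_related",
                                             cluster_keys = cl_i),
               cumulative_specific_frequency(rep, lab_i, "bulk"))
  }
  expect_error(cumulative_specific_frequency(rep, lab,
                                             "cluster_related"),
               "cluster_keys")
})
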
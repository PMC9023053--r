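# repertoire_io: parsing, singleton removal, down-sampling, pooling.

write_tsv_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_repertoire parses the VDJtools dialect and fixes freqs", {
  f <- write_tsv_lines(c(
    "count\tfreq\tcdr3nt\tcdr3aa\tv\td\tj",
    "5\t0\t.\tCASSF\tTRBV1\t.\tTRBJ1",
    "3\t0\t.\tCASTF\tTRBV1\t.\tTRBJ1",
    "2\t0\t.\tCSARVGNQPQHF\tTRBV20\t.\tTRBJ1-5"))
  rep <- read_repertoire(f)
  expect_equal(rep$clonotypes$freq, c(0.5, 0.3, 0.2))
  # the printed clonotype parses with its exact field values
  expect_equal(rep$clonotypes$cdr3aa[3], "CSARVGNQPQHF")
  expect_equal(rep$clonotypes$v[3], "TRBV20")
  expect_equal(rep$clonotypes$j[3], "TRBJ1-5")
})

test_that("read_repertoire degenerate and error cases", {
  f <- write_tsv_lines("count\tfreq\tcdr3nt\tcdr3aa\tv\td\tj")
  empty <- read_repertoire(f)
  expect_equal(n_clonotypes(empty), 0L)
  expect_equal(total_reads(empty), 0L)

  f2 <- write_tsv_lines(c("count\tfreq\tcdr3nt\tcdr3aa\tv\td",
                          "1\t1\t.\tCASSF\tTRBV1\t."))
  expect_error(read_repertoire(f2), "j")

  f3 <- write_tsv_lines(c("count\tfreq\tcdr3nt\tcdr3aa\tv\td\tj",
                          "2\t0.5\t.\tCASSF\tTRBV1\t.\tTRBJ1",
                          "1.5\t0.5\t.\tCASTF\tTRBV1\t.\tTRBJ1"))
  expect_error(read_repertoire(f3), "row 2")
})

test_that("gene labels are compared after allele stripping", {
  expect_equal(strip_allele("TRBV20-1*01"), "TRBV20-1")
  rep <- mini_rep(c(3, 2), c("CASSF", "CASTF"), v = "TRBV20-1*01")
  expect_equal(rep$clonotypes$v, rep("TRBV20-1", 2))
})

test_that("cdr3nt must translate to cdr3aa when present", {
  expect_error(
    repertoire(data.frame(count = 2, cdr3nt = "TGTGCCAGC",
                          cdr3aa = "CAT", v = "V", j = "J")),
    "translate")
  ok <- repertoire(data.frame(count = 2, cdr3nt = "TGTGCCAGC",
                              cdr3aa = "CAS", v = "V", j = "J"))
  expect_equal(n_clonotypes(ok), 1L)
})

test_that("remove_singletons filters and renormalizes", {
  rep <- mini_rep(c(5, 2, 1, 1), c("CASSF", "CASTF", "CASGF", "CATTF"))
  out <- remove_singletons(rep)
  expect_equal(out$clonotypes$count, c(5L, 2L))
  expect_equal(out$clonotypes$freq, c(5 / 7, 2 / 7))
  # original untouched
  expect_equal(n_clonotypes(rep), 4L)

  expect_equal(n_clonotypes(remove_singletons(
    mini_rep(c(1, 1), c("CASSF", "CASTF")))), 0L)
  two <- remove_singletons(mini_rep(c(2, 2), c("CASSF", "CASTF")))
  expect_equal(two$clonotypes$cdr3aa, c("CASSF", "CASTF"))
})

test_that("downsample contracts: identity, forced outcome, determinism", {
  rep <- mini_rep(c(6, 4), c("CASSF", "CASTF"))
  expect_equal(downsample(rep, 10, seed = 1)$clonotypes$count,
               c(6L, 4L))
  one <- mini_rep(10, "CASSF")
  expect_equal(downsample(one, 4, seed = 1)$clonotypes$count, 4L)
  big <- mini_rep(c(40, 30, 20, 10),
                  c("CASSF", "CASTF", "CASGF", "CATTF"))
  expect_identical(downsample(big, 37, seed = 9)$clonotypes,
                   downsample(big, 37, seed = 9)$clonotypes)
  expect_error(downsample(big, 101, seed = 1), "exceeds")
})

test_that("downsample is marginally unbiased", {
  rep <- mini_rep(c(40, 30, 20, 10),
                  c("CASSF", "CASTF", "CASGF", "CATTF"))
  n <- 25
  draws <- vapply(seq_len(1000), function(s) {
    out <- downsample(rep, n, seed = s)
    cnt <- rep(0, 4)
    cnt[match(out$clonotypes$cdr3aa, rep$clonotypes$cdr3aa)] <-
      out$clonotypes$count
    cnt
  }, numeric(4))
  expected <- n * rep$clonotypes$freq
  # hypergeometric variance, 1000 replicates
  N <- total_reads(rep)
  v <- n * rep$clonotypes$freq * (1 - rep$clonotypes$freq) *
    (N - n) / (N - 1)
  se <- sqrt(v / 1000)
  expect_true(all(abs(rowMeans(draws) - expected) <= 3 * se))
})

test_that("pool merges on the clonotype key and is order-invariant", {
  a <- mini_rep(c(3, 10), c("CASSF", "CASGF"), sample_id = "a")
  b <- mini_rep(c(4, 20), c("CASSF", "CATTF"), sample_id = "b")
  p <- pool_repertoires(list(a, b))
  expect_equal(p$clonotypes[cdr3aa == "CASSF", count], 7L)
  expect_equal(n_clonotypes(p), 3L)
  expect_equal(sum(p$clonotypes$freq), 1)

  expect_equal(pool_repertoires(list(a))$clonotypes[order(cdr3aa)],
               a$clonotypes[order(cdr3aa)])

  d1 <- mini_rep(rep(2, 10), paste0("CAS", LETTERS[1:10], "F"))
  d2 <- mini_rep(rep(2, 20), paste0("CAT", LETTERS[1:20], "F"))
  expect_equal(n_clonotypes(pool_repertoires(list(d1, d2))), 30L)

  ab_c <- pool_repertoires(list(pool_repertoires(list(a, b)), d1))
  a_bc <- pool_repertoires(list(a, pool_repertoires(list(b, d1))))
  expect_equal(ab_c$clonotypes[order(cdr3aa)][, .(cdr3aa, count)],
               a_bc$clonotypes[order(cdr3aa)][, .(cdr3aa, count)])
})

test_that("write/read round trip is stable", {
  dt <- random_fixture(60, seed = 4)
  rep <- repertoire(dt, sample_id = "rt")
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_repertoire(rep, f1)
  back <- read_repertoire(f1)
  write_repertoire(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(back$clonotypes$count, rep$clonotypes$count)
  expect_equal(back$clonotypes$freq, rep$clonotypes$freq,
               tolerance = 1e-8)
})
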
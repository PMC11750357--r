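test_that("gc_content excludes ambiguity codes and rejects empty input", {
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ACGTN"), 0.5)
  expect_equal(gc_content("acgt"), 0.5)
  expect_error(gc_content("NNNN"), "no unambiguous")
  expect_error(gc_content(""), "empty")
})

test_that("busco_envelope is median +/- k*MAD with raw MAD", {
  recs <- data.frame(gc = c(0.30, 0.32, 0.34, 0.36, 0.38),
                     coverage = c(50, 55, 60, 65, 70))
  env <- busco_envelope(recs, k = 5)
  # median 0.34, MAD 0.02 (hand arithmetic)
  expect_equal(env$gc, c(0.34 - 5 * 0.02, 0.34 + 5 * 0.02))
  expect_equal(env$coverage, c(60 - 5 * 5, 60 + 5 * 5))
  # zero spread degenerates to a point that still accepts equality
  flat <- data.frame(gc = rep(0.35, 6), coverage = rep(60, 6))
  env2 <- busco_envelope(flat)
  expect_equal(env2$gc, c(0.35, 0.35))
  rec <- list(scaffold = "s", gc = 0.35, coverage = 60)
  expect_equal(classify_scaffold(rec, env2)$verdict, "endogenized")
  expect_error(busco_envelope(recs[1:4, ]), "insufficient")
})

test_that("majority vote is strict, tie-safe and permutation-invariant", {
  expect_equal(majority_vote_taxonomy(c("insect", "insect", "virus")), "insect")
  expect_equal(majority_vote_taxonomy(c("insect", "virus")), "unassigned")
  expect_equal(majority_vote_taxonomy(character(0)), "unassigned")
  set.seed(11)
  for (i in 1:20) {
    labs <- sample(c("insect", "virus", "bacteria"), sample(1:9, 1),
                   replace = TRUE)
    expect_identical(majority_vote_taxonomy(labs),
                     majority_vote_taxonomy(sample(labs)))
  }
})

test_that("te_intervals filters strictly and merges overlaps", {
  hits <- data.frame(qstart = c(100, 350), qend = c(400, 700),
                     evalue = c(1e-20, 1e-15), length = c(120, 150))
  out <- te_intervals(hits)
  expect_equal(out, data.frame(start = 100, end = 700))
  # boundaries are strict: length must exceed 100 aa, e-value be below 1e-10
  expect_equal(nrow(te_intervals(
    data.frame(qstart = 1, qend = 50, evalue = 1e-20, length = 100))), 0L)
  expect_equal(nrow(te_intervals(
    data.frame(qstart = 1, qend = 50, evalue = 1e-10, length = 150))), 0L)
  expect_error(te_intervals(
    data.frame(qstart = 1, qend = NA, evalue = 1e-20, length = 150)),
    "malformed")
})

test_that("te_intervals equals a brute-force base-set union", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(1:8, 1)
    s <- sample(0:60, n, replace = TRUE)
    len <- sample(1:25, n, replace = TRUE)
    hits <- data.frame(qstart = s, qend = s + len,
                       evalue = 10^-runif(n, 5, 30),
                       length = sample(c(50, 150), n, replace = TRUE))
    out <- te_intervals(hits)
    keep <- hits$evalue < 1e-10 & hits$length > 100
    # brute force: the union of covered half-open base sets
    covered <- sort(unique(unlist(mapply(function(a, b) seq(a, b - 1),
                                         hits$qstart[keep], hits$qend[keep],
                                         SIMPLIFY = FALSE))))
    got <- sort(unlist(mapply(function(a, b) seq(a, b - 1), out$start,
                              out$end, SIMPLIFY = FALSE)))
    expect_equal(as.integer(got), as.integer(covered))
    # book-ended runs must be merged, so intervals are separated by gaps
    if (nrow(out) > 1)
      expect_true(all(out$start[-1] > out$end[-nrow(out)]))
  }
})

test_that("verdicts follow the evidence rules and are monotone in genes", {
  env <- busco_envelope(data.frame(gc = c(0.33, 0.34, 0.35, 0.36, 0.37),
                                   coverage = c(55, 58, 60, 62, 65)))
  inside <- list(scaffold = "a", gc = 0.35, coverage = 60)
  outside <- list(scaffold = "b", gc = 0.9, coverage = 60)
  expect_equal(classify_scaffold(inside, env)$verdict, "endogenized")
  expect_equal(classify_scaffold(outside, env)$verdict, "likely_exogenous")
  # coverage 0 against an all-positive envelope fails that metric
  expect_false(classify_scaffold(list(scaffold = "c", gc = 0.35,
                                      coverage = 0), env)$coverage_ok)
  # a eukaryotic gene rescues any verdict (monotonicity)
  for (rec in list(inside, outside)) {
    v0 <- classify_scaffold(rec, env)$verdict
    v1 <- classify_scaffold(rec, env, gene_labels = "insect")$verdict
    expect_equal(v1, "endogenized")
    if (v0 == "endogenized") expect_equal(v1, v0)
  }
  # as does a passing TE interval
  te <- data.frame(qstart = 10, qend = 500, evalue = 1e-20, length = 160)
  expect_equal(classify_scaffold(outside, env, te_hits = te)$verdict,
               "endogenized")
})

test_that("all truth EVE scaffolds are called endogenized on the mimic run", {
  fx <- mimic_fixture()
  expect_true(all(fx$res$evidence$verdict == "endogenized"))
  expect_setequal(fx$res$evidence$scaffold,
                  unique(fx$ds$truth_loci$scaffold))
})
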
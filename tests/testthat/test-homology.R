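test_that("filter_hits treats the e-value ceiling as inclusive", {
  hits <- data.frame(qseqid = "s", sseqid = "LhFV|lef-5|p01",
                     pident = 60, length = 100, mismatch = 40, gapopen = 0,
                     qstart = 1, qend = 300, sstart = 1, send = 100,
                     evalue = c(1e-3, 2e-3, 1e-50), bitscore = c(80, 70, 300))
  hits <- normalize_hits(hits)
  kept <- filter_hits(hits)
  expect_equal(kept$evalue, c(1e-3, 1e-50))
  expect_equal(nrow(filter_hits(hits[0, ])), 0L)
})

test_that("minus-strand hits are normalized to half-open forward coordinates", {
  hits <- normalize_hits(data.frame(
    qseqid = "s", sseqid = "LhFV|p74|p02", pident = 60, length = 100,
    mismatch = 0, gapopen = 0, qstart = c(101, 400), qend = c(400, 101),
    sstart = 1, send = 100, evalue = 1e-20, bitscore = 100))
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$start, c(100, 100))
  expect_equal(hits$end, c(400, 400))
  expect_equal(hits$family, c("p74", "p74"))
  expect_equal(hits$subject_virus, c("LhFV", "LhFV"))
})

test_that("call_loci merges overlapping same-strand hits, splits the rest", {
  base <- data.frame(qseqid = "s", pident = 60, length = 100, mismatch = 0,
                     gapopen = 0, sstart = 1, send = 100, evalue = 1e-20)
  h <- rbind(
    cbind(base, sseqid = "LhFV|famA|p01", qstart = 101, qend = 400,
          bitscore = 200),
    cbind(base, sseqid = "LbFV|famA|p02", qstart = 301, qend = 600,
          bitscore = 150),
    cbind(base, sseqid = "LhFV|famB|p03", qstart = 1001, qend = 1300,
          bitscore = 180))
  loci <- call_loci(normalize_hits(h), species = "sp1")
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$start, c(100, 1000))
  expect_equal(loci$end, c(600, 1300))
  # merged locus takes the family of its best-bitscore hit
  expect_equal(loci$family, c("famA", "famB"))
  expect_equal(loci$best_virus, c("LhFV", "LhFV"))
  # opposite strands never merge
  h2 <- rbind(
    cbind(base, sseqid = "LhFV|famA|p01", qstart = 101, qend = 400,
          bitscore = 200),
    cbind(base, sseqid = "LhFV|famA|p02", qstart = 400, qend = 150,
          bitscore = 150))
  expect_equal(nrow(call_loci(normalize_hits(h2))), 2L)
})

test_that("called loci are pairwise disjoint per scaffold and strand", {
  set.seed(7)
  base <- data.frame(pident = 60, length = 100, mismatch = 0, gapopen = 0,
                     sstart = 1, send = 100, evalue = 1e-20)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    s <- sample(0:3000, n, replace = TRUE)
    w <- sample(50:800, n, replace = TRUE)
    minus <- runif(n) < 0.4
    h <- data.frame(qseqid = sample(c("sA", "sB"), n, replace = TRUE),
                    sseqid = sprintf("LhFV|fam%d|p%02d",
                                     sample(1:3, n, TRUE), 1:n),
                    base[rep(1, n), ],
                    qstart = ifelse(minus, s + w, s + 1),
                    qend = ifelse(minus, s + 1, s + w),
                    bitscore = round(runif(n, 50, 300)))
    loci <- call_loci(normalize_hits(h))
    for (key in unique(paste(loci$scaffold, loci$strand))) {
      l <- loci[paste(loci$scaffold, loci$strand) == key, ]
      l <- l[order(l$start), ]
      if (nrow(l) > 1) expect_true(all(l$start[-1] >= l$end[-nrow(l)]))
    }
  }
})

test_that("orf_integrity recognizes starts, premature stops and truncation", {
  expect_equal(orf_integrity("ATGAAATAA"),
               list(orf_status = "complete", start_codon = "ATG"))
  # stop at codon 2 of a long hit-supported span truncates > 20%
  long <- paste0("ATGTAA", strrep("AAA", 20))
  expect_equal(orf_integrity(long)$orf_status, "premature_stop")
  # alternative starts are recognized
  expect_equal(orf_integrity("TTGAAACCCTAA"),
               list(orf_status = "complete", start_codon = "TTG"))
  expect_equal(orf_integrity("CTGAAACCCTAA")$start_codon, "CTG")
  # no stop inside the locus bounds
  expect_equal(orf_integrity(paste0("ATG", strrep("AAA", 10)))$orf_status,
               "incomplete")
  # no recognized start at all
  expect_equal(orf_integrity(strrep("CCC", 10))$orf_status, "incomplete")
  # minus strand: reading happens on the reverse complement
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  expect_equal(orf_integrity(rc("ATGAAATAA"), strand = "-")$orf_status,
               "complete")
  expect_error(orf_integrity("ATG"), "shorter")
})

test_that("the mimic catalog matches the truth table exactly", {
  fx <- mimic_fixture()
  truth <- fx$ds$truth_loci
  catalog <- fx$res$catalog
  expect_equal(nrow(catalog), nrow(truth))
  expect_setequal(catalog$locus_id, truth$locus_id)
  m <- merge(catalog, truth, by = "locus_id")
  expect_equal(m$family.x, m$family.y)
  expect_equal(m$orf_status.x, m$orf_status.y)
  expect_equal(m$start_codon.x, m$start_codon.y)
  # pseudogenized copies premature, intact copies complete
  expect_true(all(m$orf_status.x[m$orf_status.y == "premature_stop"] ==
                    "premature_stop"))
})
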
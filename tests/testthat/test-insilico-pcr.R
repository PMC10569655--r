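# Degenerate matching, amplicon prediction and priming classification.

test_that("a planted site is found exactly where the generator put it", {
  p <- scb_test_primers()
  loc <- generate_pair_locus(plant_spec(gap = 180L, seed = 7L))
  m <- match_primer(p$fwd, loc$genome$sequence)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, loc$truth$fwd_site_start)
  expect_equal(m$end, loc$truth$fwd_site_end)
  expect_equal(m$strand, "+")
  expect_equal(m$mismatches, 0L)

  mr <- match_primer(p$rev, loc$genome$sequence)
  expect_equal(mr$start, loc$truth$rev_site_start)
  expect_equal(mr$strand, "-")
})

test_that("a 3'-terminal mismatch abolishes the site even with slack", {
  p <- scb_test_primers()
  loc <- generate_pair_locus(plant_spec(gap = 180L, seed = 7L))
  tpl <- loc$genome$sequence
  # the fwd primer matches the plus strand; its 3' end is the site's right edge
  pos3 <- loc$truth$fwd_site_end
  cur <- substr(tpl, pos3, pos3)
  # replace with a base incompatible with the primer's 3'-terminal A
  substr(tpl, pos3, pos3) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  m <- match_primer(p$fwd, tpl, max_mismatch = 2L)
  expect_false(loc$truth$fwd_site_start %in% m$start[m$strand == "+"])

  # the same substitution outside the 3' window is tolerated at max_mismatch 2
  tpl2 <- loc$genome$sequence
  pos5 <- loc$truth$fwd_site_start
  cur5 <- substr(tpl2, pos5, pos5)
  substr(tpl2, pos5, pos5) <- setdiff(c("A", "C", "G", "T"), c(cur5, "C"))[1]
  m2 <- match_primer(p$fwd, tpl2, max_mismatch = 2L)
  expect_true(loc$truth$fwd_site_start %in% m2$start[m2$strand == "+"])
})

test_that("zero-mismatch matching equals the exhaustive-expansion oracle", {
  p <- scb_test_primers()
  set.seed(27)
  for (k in 1:12) {
    tpl <- random_dna(1200)
    # implant a couple of concrete expansions, either strand
    for (pr in list(p$fwd, p$rev)) {
      ex <- expand_degenerate(pr$sequence)
      for (j in 1:2) {
        word <- sample(ex, 1)
        if (stats::runif(1) < 0.5) word <- revcomp(word)
        off <- sample.int(nchar(tpl) - nchar(word) + 1L, 1L)
        substr(tpl, off, off + nchar(word) - 1L) <- word
      }
    }
    for (pr in list(p$fwd, p$rev)) {
      expect_equal(match_keys(match_primer(pr, tpl)),
                   match_oracle(pr$sequence, tpl))
    }
  }
})

test_that("template N never matches and match counts grow with tolerance", {
  p <- scb_test_primers()
  set.seed(28)
  ex <- expand_degenerate(p$fwd$sequence)[1]
  tpl <- paste0(random_dna(200), ex, random_dna(200))
  withN <- tpl
  substr(withN, 210, 210) <- "N"
  expect_equal(nrow(match_primer(p$fwd, tpl)), 1L)
  expect_equal(nrow(match_primer(p$fwd, withN)), 0L)

  counts <- vapply(0:3, function(mm)
    nrow(match_primer(p$fwd, tpl, max_mismatch = mm)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("amplicon size equals the planted outer-edge distance", {
  p <- scb_test_primers()
  loc <- generate_pair_locus(plant_spec(target_amplicon = 600L, seed = 55L))
  amp <- predict_amplicons(p$fwd, p$rev, loc$genome$sequence)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 600L)
  expect_equal(amp$length, amp$end - amp$start + 1L)
})

test_that("lone or outward-facing sites never yield amplicons", {
  p <- scb_test_primers()
  set.seed(29)
  fwd_word <- expand_degenerate(p$fwd$sequence)[5]
  rev_word <- expand_degenerate(p$rev$sequence)[5]

  lone <- paste0(random_dna(300), fwd_word, random_dna(300))
  expect_equal(nrow(predict_amplicons(p$fwd, p$rev, lone)), 0L)

  # outward: minus-strand fwd site left of a plus-strand rev site
  outward <- paste0(random_dna(200), revcomp(fwd_word), random_dna(300),
                    rev_word, random_dna(200))
  expect_equal(nrow(predict_amplicons(p$fwd, p$rev, outward)), 0L)

  inward <- paste0(random_dna(200), fwd_word, random_dna(300),
                   revcomp(rev_word), random_dna(200))
  expect_equal(nrow(predict_amplicons(p$fwd, p$rev, inward)), 1L)

  expect_error(predict_amplicons(p$fwd, p$fwd, inward), "distinct")
})

test_that("amplicon prediction is symmetric in primer labels", {
  p <- scb_test_primers()
  loc <- generate_pair_locus(plant_spec(gap = 300L, seed = 66L))
  a <- predict_amplicons(p$fwd, p$rev, loc$genome$sequence)
  b <- predict_amplicons(p$rev, p$fwd, loc$genome$sequence)
  expect_equal(a[, c("start", "end", "length")], b[, c("start", "end", "length")])
})

test_that("priming classes reproduce the published variant comments", {
  p <- scb_test_primers()
  cls <- function(v, ref, pr) as.character(classify_priming(v, ref, pr, p$table))

  expect_equal(cls("YFHF", "YFHF", p$fwd), "will_prime")
  expect_equal(cls("YFHx", "YFHF", p$fwd), "will_likely_prime")
  expect_equal(cls("YxHF", "YFHF", p$fwd), "might_not_prime")
  expect_equal(cls("xFHF", "YFHF", p$fwd), "might_not_prime")
  expect_equal(cls("YHHF", "YFHF", p$fwd), "will_not_prime")
  expect_equal(cls("HHHF", "YFHF", p$fwd), "will_not_prime")

  expect_equal(cls("ETxRQ", "ETxRQ", p$rev), "will_likely_prime")
  expect_equal(cls("ETxRx", "ETxRQ", p$rev), "will_likely_prime")
  expect_equal(cls("ESxRQ", "ETxRQ", p$rev), "might_not_prime")

  # strain-panel variants
  expect_equal(cls("ETIRQ", "ETxRQ", p$rev), "will_prime")
  expect_equal(cls("ETVRQ", "ETxRQ", p$rev), "will_prime")
  expect_equal(cls("YFHY", "YFHF", p$fwd), "will_likely_prime")
  expect_equal(cls("EAVRQ", "ETxRQ", p$rev), "might_not_prime")
  expect_equal(cls("EAIRQ", "ETxRQ", p$rev), "might_not_prime")

  expect_error(classify_priming("YFH", "YFHF", p$fwd, p$table), "same length")

  # ordering of the class scale
  lv <- levels(classify_priming("YFHF", "YFHF", p$fwd, p$table))
  expect_equal(lv, c("will_prime", "will_likely_prime", "might_not_prime",
                     "will_not_prime"))
})
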
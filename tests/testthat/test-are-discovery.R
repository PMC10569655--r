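# EM motif discovery, palindromicity and empirical significance.

test_that("planted 18-mer sites are recovered with a monotone likelihood", {
  gen <- generate_are_set(n = 7, len = 500, noise = 0.1, seed = 11)
  m <- discover_motif(gen$seqs, wmin = 18, wmax = 18, seed = 3)
  expect_s3_class(m, "motif_model")
  expect_true(all(abs(rowSums(m$pwm) - 1) < 1e-9))

  merged <- dplyr::inner_join(m$sites, gen$truth, by = "seq_id",
                              suffix = c("_fit", "_truth"))
  n_close <- sum(abs(merged$offset_fit - merged$offset_truth) <= 1)
  expect_gte(n_close, 6L)

  expect_true(all(diff(m$llr_trace) >= -1e-8))

  # OOPS forces a site in every sequence
  m_oops <- discover_motif(gen$seqs, wmin = 18, wmax = 18, mode = "oops", seed = 3)
  expect_equal(nrow(m_oops$sites), 7L)
  merged_oops <- dplyr::inner_join(m_oops$sites, gen$truth, by = "seq_id",
                                   suffix = c("_fit", "_truth"))
  expect_gte(sum(abs(merged_oops$offset_fit - merged_oops$offset_truth) <= 1), 6L)
})

test_that("motif recovery is strand-aware and reverse-complement invariant", {
  consensus <- "ATGGCCGTTAACTCGCAA" # deliberately non-palindromic
  gen <- generate_are_set(n = 7, len = 400, consensus = consensus,
                          noise = 0.05, rc_fraction = 0.5, seed = 21)
  m <- discover_motif(gen$seqs, wmin = 18, wmax = 18, seed = 3)
  merged <- dplyr::inner_join(m$sites, gen$truth, by = "seq_id",
                              suffix = c("_fit", "_truth"))
  expect_gte(sum(abs(merged$offset_fit - merged$offset_truth) <= 1), 6L)

  # reverse-complement every input: same sites in mirrored coordinates
  rc_seqs <- stats::setNames(vapply(gen$seqs, revcomp, ""), names(gen$seqs))
  m2 <- discover_motif(rc_seqs, wmin = 18, wmax = 18, seed = 3)
  lens <- nchar(gen$seqs)[m2$sites$seq_id]
  mirrored <- unname(lens - 18 + 2 - m2$sites$offset)
  merged2 <- dplyr::inner_join(
    tibble::tibble(seq_id = m2$sites$seq_id, offset = mirrored),
    gen$truth, by = "seq_id", suffix = c("_fit", "_truth"))
  expect_gte(sum(abs(merged2$offset_fit - merged2$offset_truth) <= 1), 6L)
})

test_that("width calibration picks a motif covering the planted site", {
  gen <- generate_are_set(n = 5, len = 260, noise = 0.05, seed = 41)
  m <- discover_motif(gen$seqs, wmin = 17, wmax = 19, seed = 5,
                      width_shuffles = 3)
  expect_true(m$width %in% 17:19)
  merged <- dplyr::inner_join(m$sites, gen$truth, by = "seq_id",
                              suffix = c("_fit", "_truth"))
  expect_gte(sum(abs(merged$offset_fit - merged$offset_truth) <= 2), 4L)
})

test_that("input validation lists offending sequences", {
  expect_error(discover_motif(c("ACGT", "ACGT"), wmin = 4, wmax = 4), "at least 3")
  seqs <- c(strrep("ACGT", 20), strrep("ACGT", 20), "ACGTACG")
  expect_error(discover_motif(seqs, wmin = 15, wmax = 20), "shorter.*3")
})

test_that("palindromicity scores inverted repeats and poly-A correctly", {
  half <- "AAACGGACC"
  pal <- paste0(half, revcomp(half))
  w <- nchar(pal)
  pwm_of <- function(s) {
    ch <- strsplit(s, "")[[1]]
    m <- matrix(0.02, nrow = length(ch), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    m[cbind(seq_along(ch), match(ch, c("A", "C", "G", "T")))] <- 0.94
    m
  }
  expect_equal(palindromicity(pwm_of(pal)), 1.0)
  polyA <- matrix(rep(c(1, 0, 0, 0), each = 10), nrow = 10,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_equal(palindromicity(polyA), 0)
  expect_lt(palindromicity(pwm_of(strrep("A", w))), 0.5)

  # palindromized average of any PWM is at least as palindromic
  set.seed(44)
  for (k in 1:10) {
    p <- matrix(stats::rexp(4 * 12), ncol = 4)
    p <- p / rowSums(p)
    colnames(p) <- c("A", "C", "G", "T")
    rc <- p[rev(seq_len(nrow(p))), c(4, 3, 2, 1)]
    colnames(rc) <- c("A", "C", "G", "T")
    expect_gte(palindromicity((p + rc) / 2) + 1e-12, palindromicity(p))
  }
})

test_that("empirical significance floors for planted motifs, not for noise", {
  gen <- generate_are_set(n = 5, len = 250, noise = 0.05, seed = 51)
  m <- discover_motif(gen$seqs, wmin = 18, wmax = 18, seed = 3)
  sig <- motif_significance(m, gen$seqs, n_shuffles = 49, seed = 9)
  expect_equal(sig, 1 / 50)

  # on pure noise the typical (median) significance is unremarkable; single
  # datasets can land in the tail because the shuffle null conditions on the
  # observed dinucleotide counts
  sigs <- vapply(1:5, function(k) {
    set.seed(51 + k)
    noise_seqs <- replicate(5, paste(sample(c("A", "C", "G", "T"), 250, TRUE),
                                     collapse = ""))
    m0 <- discover_motif(noise_seqs, wmin = 18, wmax = 18, seed = 3)
    suppressWarnings(motif_significance(m0, noise_seqs, n_shuffles = 19, seed = 9))
  }, 0)
  expect_gt(stats::median(sigs), 0.05)

  expect_error(motif_significance(m, gen$seqs, n_shuffles = 0), "at least 1")
  expect_warning(motif_significance(m, gen$seqs, n_shuffles = 5, seed = 2),
                 "coarse")
})

test_that("dinucleotide shuffling preserves composition and endpoints", {
  set.seed(61)
  for (k in 1:8) {
    s <- random_dna(sample(100:300, 1), gc = stats::runif(1, 0.3, 0.7))
    sh <- dinuc_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, nchar(sh), nchar(sh)), substr(s, nchar(s), nchar(s)))
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
  }
})

test_that("discovery is deterministic given the seed", {
  gen <- generate_are_set(n = 5, len = 250, noise = 0.1, seed = 71)
  m1 <- discover_motif(gen$seqs, wmin = 17, wmax = 19, seed = 4, width_shuffles = 3)
  m2 <- discover_motif(gen$seqs, wmin = 17, wmax = 19, seed = 4, width_shuffles = 3)
  expect_identical(m1$width, m2$width)
  expect_identical(m1$pwm, m2$pwm)
  expect_identical(m1$sites, m2$sites)
})
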
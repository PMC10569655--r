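# Homology search, collocation, orientation and intergenic extraction.

test_that("an exact proteome member is the top hit with identity 1", {
  q <- synthetic_queries()$receptor
  set.seed(3)
  prot <- tibble::tibble(
    contig_id = "c1", start = c(1L, 1000L), end = c(648L, 1930L),
    strand = "+", locus_tag = c("self", "other"),
    protein = c(q, paste(sample(AA20, 300, TRUE), collapse = "")))
  hits <- find_homologs(prot, q)
  expect_equal(hits$locus_tag[1], "self")
  expect_equal(hits$identity[1], 1.0)
  expect_lt(hits$evalue[1], 1e-100)
})

test_that("random decoy proteomes yield no hits at the 0.02 threshold", {
  q <- synthetic_queries()$receptor
  set.seed(42)
  decoys <- tibble::tibble(
    contig_id = paste0("c", 1:30), start = 1L, end = 453L, strand = "+",
    locus_tag = paste0("d", 1:30),
    protein = replicate(30, paste(sample(AA20, 150, TRUE), collapse = "")))
  expect_equal(nrow(find_homologs(decoys, q)), 0L)
})

test_that("hit scores agree with an exhaustive Smith-Waterman oracle", {
  set.seed(9)
  q <- paste(sample(AA20, 60, TRUE), collapse = "")
  prot <- tibble::tibble(
    contig_id = paste0("c", 1:6), start = 1L, end = 243L, strand = "+",
    locus_tag = paste0("p", 1:6),
    protein = c(q,
                mutate_protein(q, 0.3),
                replicate(4, paste(sample(AA20, 80, TRUE), collapse = ""))))
  hits <- find_homologs(prot, q, evalue_max = Inf)
  oracle <- vapply(prot$protein, sw_score_oracle, 0, b = q)
  expect_equal(hits$score[match(prot$locus_tag, hits$locus_tag)],
               unname(oracle), tolerance = 1e-8)
})

test_that("a diverged receptor variant is still recovered as a hit", {
  q <- synthetic_queries()$receptor
  set.seed(5)
  variant <- mutate_protein(q, 0.4) # ~60% identity
  prot <- tibble::tibble(contig_id = "c1", start = 1L, end = 648L, strand = "+",
                         locus_tag = "var", protein = variant)
  hits <- find_homologs(prot, q)
  expect_equal(nrow(hits), 1L)
  expect_gt(hits$identity[1], 0.45)
})

test_that("pairing respects the maximum intergenic distance exactly", {
  # receptor CDS [1,100]; synthase CDS starting at 700 leaves a 599 bp gap
  rec <- toy_hits("c1", 1, 100, "-", "r")
  syn599 <- toy_hits("c1", 700, 1300, "+", "s")
  expect_equal(nrow(pair_colocated(syn599, rec)), 1L)
  expect_equal(pair_colocated(syn599, rec)$gap, 599L)

  syn601 <- toy_hits("c1", 702, 1300, "+", "s")
  expect_equal(pair_colocated(syn601, rec, max_intergenic = 600L)$gap, integer(0))

  # overlap clamps to gap 0
  syn_ov <- toy_hits("c1", 90, 700, "+", "s")
  expect_equal(pair_colocated(syn_ov, rec)$gap, 0L)
})

test_that("all-pairs combinations and cross-contig exclusion are honoured", {
  rec <- toy_hits("c1", 2000, 2600, "-", "r")
  syn <- toy_hits("c1", c(1000, 2700, 3300), c(1900, 3200, 3900), "+", "s")
  pairs <- pair_colocated(syn, rec)
  # brute-force gaps: 2000-1900-1=99; 2700-2600-1=99; 3300-2600-1=699
  expect_equal(nrow(pairs), 2L)
  expect_setequal(pairs$gap, c(99L, 99L))
  expect_equal(nrow(pair_colocated(syn, rec, max_intergenic = 700L)), 3L)

  rec2 <- toy_hits("c2", 2000, 2600, "-", "r")
  expect_equal(nrow(pair_colocated(syn, rec2)), 0L)
  expect_equal(nrow(pair_colocated(syn[0, ], rec)), 0L)
})

test_that("orientation classes follow left/right strands", {
  rec <- toy_hits("c1", 100, 700, "-", "r")
  syn <- toy_hits("c1", 900, 1800, "+", "s")
  expect_equal(pair_colocated(syn, rec)$orientation, "divergent")

  rec_p <- toy_hits("c1", 100, 700, "+", "r")
  syn_m <- toy_hits("c1", 900, 1800, "-", "s")
  expect_equal(pair_colocated(syn_m, rec_p)$orientation, "convergent")

  expect_equal(pair_colocated(syn, rec_p)$orientation, "tandem")
})

test_that("orientation is invariant under reverse-complementing the contig", {
  L <- 5000L
  flip <- function(h) {
    tibble::tibble(contig_id = h$contig_id,
                   start = L - h$end + 1L, end = L - h$start + 1L,
                   strand = ifelse(h$strand == "+", "-", "+"),
                   locus_tag = h$locus_tag, protein = h$protein,
                   query_id = h$query_id, score = h$score, bits = h$bits,
                   evalue = h$evalue, identity = h$identity)
  }
  set.seed(21)
  for (k in 1:12) {
    s1 <- sort(sample(1:2000, 2))
    s2 <- sort(sample(2500:4500, 2))
    rec <- toy_hits("c1", s1[1], s1[2], sample(c("+", "-"), 1), "r")
    syn <- toy_hits("c1", s2[1], s2[2], sample(c("+", "-"), 1), "s")
    p1 <- pair_colocated(syn, rec, max_intergenic = 5000L)
    p2 <- pair_colocated(flip(syn), flip(rec), max_intergenic = 5000L)
    expect_equal(p1$orientation, p2$orientation)
    expect_equal(p1$gap, p2$gap)
  }
})

test_that("orientation census matches planted ground truth and sums to n", {
  specs <- c(rep("divergent", 7), rep("convergent", 2), "tandem")
  loci <- lapply(seq_along(specs), function(i)
    generate_pair_locus(plant_spec(orientation = specs[i], gap = 150L, seed = 100L + i),
                        contig_id = sprintf("cen_%02d", i)))
  truth <- do.call(rbind, lapply(loci, `[[`, "truth"))
  pairs <- do.call(rbind, lapply(loci, function(l) {
    f <- l$genome$features
    rec <- f[grepl("_rec", f$locus_tag), ]
    syn <- f[grepl("_syn", f$locus_tag), ]
    pair_colocated(
      dplyr::mutate(syn, query_id = "s", score = 1, bits = 1, evalue = 0, identity = 1),
      dplyr::mutate(rec, query_id = "r", score = 1, bits = 1, evalue = 0, identity = 1))
  }))
  cen <- orientation_census(pairs)
  expect_equal(cen$n[cen$orientation == "divergent"], 7L)
  expect_equal(cen$n[cen$orientation == "convergent"], 2L)
  expect_equal(cen$n[cen$orientation == "tandem"], 1L)
  expect_equal(sum(cen$n), nrow(pairs))

  empty <- orientation_census(pair_colocated(toy_hits("c1", 1, 10, "+")[0, ],
                                             toy_hits("c1", 1, 10, "+")[0, ]))
  expect_equal(empty$n, c(0L, 0L, 0L))
})

test_that("intergenic extraction returns the exact planted gap sequence", {
  loc <- generate_pair_locus(plant_spec(gap = 180L, seed = 7L))
  f <- loc$genome$features
  rec <- f[grepl("_rec", f$locus_tag), ]
  syn <- f[grepl("_syn", f$locus_tag), ]
  pair <- pair_colocated(
    dplyr::mutate(syn, query_id = "s", score = 1, bits = 1, evalue = 0, identity = 1),
    dplyr::mutate(rec, query_id = "r", score = 1, bits = 1, evalue = 0, identity = 1))
  expect_equal(pair$orientation, "divergent")
  ig <- intergenic_sequence(pair[1, ], loc$genome)
  expect_equal(nchar(ig), 180L)
  expect_equal(ig, substr(loc$genome$sequence, loc$truth$receptor_end + 1L,
                          loc$truth$synthase_start - 1L))

  conv <- pair
  conv$orientation <- "convergent"
  expect_error(intergenic_sequence(conv[1, ], loc$genome), "divergent")

  overlapping <- pair
  overlapping$intergenic_start <- 500L
  overlapping$intergenic_end <- 499L
  expect_equal(intergenic_sequence(overlapping[1, ], loc$genome), "")
})

test_that("every reported pair honours the distance bound", {
  set.seed(14)
  syn <- toy_hits("c1", seq(1, 20000, by = 1500), seq(700, 20700, by = 1500), "+", "s")
  rec <- toy_hits("c1", seq(400, 20400, by = 2100), seq(1100, 21100, by = 2100), "-", "r")
  for (cap in c(100L, 600L, 2000L)) {
    pairs <- pair_colocated(syn, rec, max_intergenic = cap)
    expect_true(all(pairs$gap <= cap))
  }
})
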
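# Fixture generator: round trips, cohort bookkeeping, determinism.

test_that("a planted divergent locus round-trips through the pair finder", {
  loc <- generate_pair_locus(plant_spec(gap = 180L, seed = 7L))
  q <- synthetic_queries()
  prot <- cds_features(loc$genome)
  rec <- find_homologs(prot, q$receptor, "receptor")
  syn <- find_homologs(prot, q$synthase, "synthase")
  pairs <- pair_colocated(syn, rec)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$orientation, "divergent")
  expect_equal(pairs$gap, 180L)
  expect_equal(pairs$receptor_start, loc$truth$receptor_start)
  expect_equal(pairs$synthase_end, loc$truth$synthase_end)
})

test_that("incompatible variant loci yield no amplicon, compatible exactly one", {
  p <- scb_test_primers()
  # mimics the isolate with receptor YHHF + synthase ESVRQ
  mu0iv2 <- generate_pair_locus(plant_spec(receptor_variant = "YHHF",
                                           synthase_variant = "ESVRQ",
                                           gap = 315L, seed = 81L))
  expect_equal(nrow(predict_amplicons(p$fwd, p$rev, mu0iv2$genome$sequence)), 0L)
  expect_true(is.na(mu0iv2$truth$expected_amplicon))

  # mimics the isolate with receptor HHHF + synthase EAIRQ
  mu2iii1 <- generate_pair_locus(plant_spec(receptor_variant = "HHHF",
                                            synthase_variant = "EAIRQ",
                                            gap = 345L, seed = 82L))
  expect_equal(nrow(predict_amplicons(p$fwd, p$rev, mu2iii1$genome$sequence)), 0L)

  ok <- generate_pair_locus(plant_spec(receptor_variant = "YFHF",
                                       synthase_variant = "ETLRQ",
                                       gap = 200L, seed = 83L))
  amp <- predict_amplicons(p$fwd, p$rev, ok$genome$sequence)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, ok$truth$expected_amplicon)
})

test_that("a planted operator is recoverable from the intergenic regions", {
  are <- list(consensus = "AAACGGACCGGTCCGTTT", offset = 60L)
  loci <- lapply(1:4, function(i)
    generate_pair_locus(plant_spec(gap = 250L, seed = 90L + i,
                                   are = list(consensus = are$consensus,
                                              offset = 40L + 17L * i)),
                        contig_id = sprintf("arefix_%d", i)))
  igs <- vapply(loci, function(l)
    substr(l$genome$sequence, l$truth$receptor_end + 1L, l$truth$synthase_start - 1L),
    "")
  offsets <- vapply(loci, function(l) l$truth$are_start - l$truth$receptor_end, 0L)
  m <- discover_motif(igs, wmin = 18, wmax = 18, seed = 2)
  fit_off <- m$sites$offset[order(m$sites$seq_id)]
  expect_true(all(abs(fit_off - offsets) <= 1))
})

test_that("cohort bookkeeping matches the sidecar truth exactly", {
  co <- generate_cohort(40, seed = 5)
  expect_equal(nrow(co$truth), 40L)
  expect_length(co$genomes, 40L)

  d <- withr::local_tempdir()
  write_fixture_bundle(co, d, "cohort")
  reread <- readr::read_tsv(file.path(d, "cohort_truth.tsv"),
                            show_col_types = FALSE)
  expect_equal(reread$receptor_variant, co$truth$receptor_variant)
  expect_equal(reread$orientation, co$truth$orientation)

  counts <- count_motif_patterns(reread$receptor_variant,
                                 unique(co$truth$receptor_variant))
  in_mem <- table(co$truth$receptor_variant)
  expect_equal(counts$count, as.integer(in_mem[counts$pattern]),
               ignore_attr = TRUE)

  cen <- table(factor(co$truth$orientation,
                      levels = c("divergent", "convergent", "tandem")))
  expect_gt(cen[["divergent"]], cen[["convergent"]])
})

test_that("fixture generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co1 <- generate_cohort(4, seed = 12)
  co2 <- generate_cohort(4, seed = 12)
  write_fixture_bundle(co1, d1, "fix")
  write_fixture_bundle(co2, d2, "fix")
  for (f in c("fix.gbk", "fix.gff3", "fix.fasta", "fix_truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  co3 <- generate_cohort(4, seed = 13)
  expect_false(identical(co1$genomes[[1]]$sequence, co3$genomes[[1]]$sequence))
})

test_that("invalid specifications are rejected", {
  expect_error(generate_cohort(0), "positive")
  expect_error(generate_cohort(3, orientation_mix = c(divergent = 0.5)), "1")
  expect_error(plant_spec(gap = -5), "gap")
  expect_error(plant_spec(target_amplicon = 100L), "too small")
  expect_error(plant_spec(are = list(consensus = strrep("A", 30), offset = 160L),
                          gap = 180L), "fit")
  expect_error(plant_spec(receptor_variant = "YFH"), "receptor_variant")
})

test_that("a single-locus cohort drives every downstream stage", {
  co <- generate_cohort(1, seed = 99)
  cfg <- screen_config(are_wmin = 18L, are_wmax = 18L, seed = 1L)
  rep <- suppressMessages(run_screen(cfg, co$genomes))
  expect_s3_class(rep, "screen_report")
  expect_equal(nrow(rep$pairs), 1L)
  expect_equal(sum(rep$census$n), 1L)
})
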
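# Synthetic GC-rich genome fixtures: planted synthase/receptor CDS pairs in
# controlled orientations with controlled binding-site motif variants and
# optional planted palindromic operators, plus machine-readable ground truth.
# These emulate the screen's study conditions at desk scale; they do not
# simulate sequencing error or PCR artifacts.

.receptor_motif_aa <- 25L # context YFHFPSKER at receptor positions 25..33
.synthase_motif_aa <- 55L # context ET{ILV}RQSG at synthase positions 55..61
.receptor_len <- 215L
.synthase_len <- 310L

.sample_aa <- function(n) {
  # filler residue distribution loosely matching a GC-rich proteome
  w <- c(A = 12, R = 7, N = 2, D = 5, C = 1, Q = 3, E = 5, G = 9, H = 2, I = 3,
         L = 9, K = 2, M = 2, F = 3, P = 6, S = 5, T = 6, W = 1, Y = 2, V = 8)
  sample(names(w), n, replace = TRUE, prob = w)
}

.scrub_patterns <- function(prot, keep_start, keep_end) {
  # remove accidental anchor-context matches outside the planted window
  pats <- c("YFHF", "E[TSA][ILVM]RQ")
  repeat {
    hit <- FALSE
    for (p in pats) {
      m <- gregexpr(p, prot)[[1]]
      for (s in m[m > 0]) {
        if (s >= keep_start - 6L && s <= keep_end) next
        hit <- TRUE
        substr(prot, s, s) <- .sample_aa(1L)
      }
    }
    if (!hit) return(prot)
  }
}

#' Synthetic stand-in query proteins
#'
#' Deterministic synthetic receptor (TetR-like, YFHFPSKER context at
#' positions 25-33) and synthase (AfsA-like, ETLRQSG context at positions
#' 55-61) proteins used as homology-search queries throughout the test
#' fixtures. They are synthetic stand-ins, not database accessions.
#'
#' @return named list with `receptor` and `synthase` amino-acid strings.
#' @export
synthetic_queries <- function() {
  .with_seed(424242L, {
    rec <- paste(c("M", .sample_aa(.receptor_len - 1L)), collapse = "")
    substr(rec, .receptor_motif_aa, .receptor_motif_aa + 8L) <- "YFHFPSKER"
    rec <- .scrub_patterns(rec, .receptor_motif_aa, .receptor_motif_aa + 8L)
    syn <- paste(c("M", .sample_aa(.synthase_len - 1L)), collapse = "")
    substr(syn, .synthase_motif_aa, .synthase_motif_aa + 6L) <- "ETLRQSG"
    syn <- .scrub_patterns(syn, .synthase_motif_aa, .synthase_motif_aa + 6L)
    list(receptor = rec, synthase = syn)
  })
}

.default_are <- function() {
  half <- "AAACGGACC"
  paste0(half, revcomp(half)) # 18 bp perfect inverted repeat
}

#' Specification for one planted gene-pair locus
#'
#' @param orientation `"divergent"`, `"convergent"` or `"tandem"`.
#' @param gap intergenic gap in bp (>= 0); ignored when `target_amplicon`
#'   is given.
#' @param receptor_variant 4-residue binding-site variant (e.g. `"YFHF"`,
#'   `"YHHF"`).
#' @param synthase_variant 5-residue variant (e.g. `"ETLRQ"`, `"ESVRQ"`).
#' @param are `NULL`, or `list(consensus =, offset =)` planting a motif at a
#'   1-based offset within the intergenic gap.
#' @param identity target protein identity to the synthetic query proteins,
#'   in \[0.3, 1\].
#' @param seed per-locus seed.
#' @param target_amplicon optional expected product size in bp
#'   (outer primer edge to outer edge); sets the gap accordingly.
#' @param flank flanking background length on each side.
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(orientation = "divergent", gap = 180L,
                       receptor_variant = "YFHF", synthase_variant = "ETLRQ",
                       are = NULL, identity = 1.0, seed = 1L,
                       target_amplicon = NULL, flank = 150L) {
  stopifnot(orientation %in% c("divergent", "convergent", "tandem"),
            nchar(receptor_variant) == 4L, nchar(synthase_variant) == 5L,
            identity >= 0.3, identity <= 1.0)
  # distance from the receptor-side primer outer edge to the synthase-side
  # outer edge is gap + 282 bp under the fixed context placements
  if (!is.null(target_amplicon)) {
    gap <- as.integer(target_amplicon) - 282L
    if (gap < 0L) stop("target_amplicon too small for the context placements", call. = FALSE)
  }
  if (gap < 0L) stop("intergenic gap must be >= 0", call. = FALSE)
  if (!is.null(are)) {
    stopifnot(is.list(are), !is.null(are$consensus), !is.null(are$offset))
    if (are$offset < 1L || are$offset + nchar(are$consensus) - 1L > gap) {
      stop("planted motif does not fit in the intergenic gap", call. = FALSE)
    }
  }
  structure(list(orientation = orientation, gap = as.integer(gap),
                 receptor_variant = toupper(receptor_variant),
                 synthase_variant = toupper(synthase_variant),
                 are = are, identity = identity, seed = as.integer(seed),
                 flank = as.integer(flank)),
            class = "plant_spec")
}

.gc_background <- function(n, gc = 0.7) {
  if (n == 0L) return("")
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)), collapse = "")
}

.mutate_to_identity <- function(prot, identity, protect) {
  L <- nchar(prot)
  k <- round((1 - identity) * L)
  if (k == 0L) return(prot)
  cand <- setdiff(2:L, protect)
  pos <- sample(cand, min(k, length(cand)))
  for (p in pos) {
    cur <- substr(prot, p, p)
    repl <- sample(setdiff(.aa20, cur), 1L)
    substr(prot, p, p) <- repl
  }
  prot
}

# reverse-translate a protein; within [ctx_start, ctx_end] (aa coords) codons
# are drawn from the intersection with the primer's coding-sense codon
# pattern when the residue allows it, so compatible variants really carry
# primer-matchable sites
.reverse_translate <- function(prot, table, ctx_start = 0L, ctx_end = -1L,
                               ctx_pattern = NULL) {
  res <- strsplit(prot, "")[[1]]
  cods <- vapply(seq_along(res), function(i) {
    rcods <- codons_for(res[i], table)
    rfreq <- table$freq[match(rcods, table$codon)]
    if (i >= ctx_start && i <= ctx_end && !is.null(ctx_pattern)) {
      j <- i - ctx_start + 1L
      pat <- substr(ctx_pattern, 3L * j - 2L, 3L * j)
      allowed <- expand_degenerate(pat)
      inter <- intersect(rcods, allowed)
      if (length(inter) > 0L) {
        wt <- rfreq[match(inter, rcods)]
        return(inter[sample.int(length(inter), 1L, prob = wt)])
      }
    }
    rcods[sample.int(length(rcods), 1L, prob = rfreq)]
  }, character(1))
  paste(c(cods, "TGA"), collapse = "")
}

#' Generate one synthetic gene-pair locus with ground truth
#'
#' Emits a single-contig genome carrying a receptor and a synthase CDS in
#' the requested orientation with the requested intergenic gap and
#' binding-site variants. Proteins derive from [synthetic_queries()] at the
#' requested identity (context windows protected); coding sequences are
#' drawn from the codon usage table, with context codons sampled from the
#' primer-compatible intersection whenever the variant residue permits.
#' Background is order-0 at 70% GC, and accidental primer sites are removed
#' by rejection sampling. Deterministic given `spec$seed`.
#'
#' @param spec a [plant_spec()].
#' @param table codon usage table.
#' @param contig_id contig name.
#' @return list with `genome` (a [genome_record()]) and `truth` (one-row
#'   tibble incl. planted primer-site coordinates and the expected amplicon
#'   size, NA when a variant is primer-incompatible).
#' @export
generate_pair_locus <- function(spec, table = codon_usage_table(),
                                contig_id = "synthfix_001") {
  stopifnot(inherits(spec, "plant_spec"))
  pol <- scb_policies()
  fwd_primer <- design_primer(pol$scb_F$context, pol$scb_F$policy, table,
                              role = "receptor", name = "scb_F", motif_len = 4L)
  rev_primer <- design_primer(pol$scb_R$context, pol$scb_R$policy, table,
                              role = "synthase", name = "scb_R", motif_len = 5L)
  fwd_coding <- fwd_primer$coding
  rev_coding <- rev_primer$coding
  q <- synthetic_queries()

  .with_seed(spec$seed, {
    rec <- q$receptor
    substr(rec, .receptor_motif_aa, .receptor_motif_aa + 3L) <- spec$receptor_variant
    syn <- q$synthase
    substr(syn, .synthase_motif_aa, .synthase_motif_aa + 4L) <- spec$synthase_variant
    rec_protect <- .receptor_motif_aa:(.receptor_motif_aa + 8L)
    syn_protect <- .synthase_motif_aa:(.synthase_motif_aa + 6L)
    rec <- .mutate_to_identity(rec, spec$identity, rec_protect)
    rec <- .scrub_patterns(rec, .receptor_motif_aa, .receptor_motif_aa + 8L)
    syn <- .mutate_to_identity(syn, spec$identity, syn_protect)
    syn <- .scrub_patterns(syn, .synthase_motif_aa, .synthase_motif_aa + 6L)

    for (attempt in 1:25) {
      rec_cds <- .reverse_translate(rec, table, .receptor_motif_aa,
                                    .receptor_motif_aa + 8L, fwd_coding)
      syn_cds <- .reverse_translate(syn, table, .synthase_motif_aa,
                                    .synthase_motif_aa + 6L, rev_coding)
      gapseq <- .gc_background(spec$gap)
      if (!is.null(spec$are)) {
        substr(gapseq, spec$are$offset,
               spec$are$offset + nchar(spec$are$consensus) - 1L) <- toupper(spec$are$consensus)
      }
      fl1 <- .gc_background(spec$flank); fl2 <- .gc_background(spec$flank)

      lay <- switch(spec$orientation,
        divergent = list(left = revcomp(rec_cds), right = syn_cds,
                         rec_strand = "-", syn_strand = "+"),
        convergent = list(left = rec_cds, right = revcomp(syn_cds),
                          rec_strand = "+", syn_strand = "-"),
        tandem = list(left = rec_cds, right = syn_cds,
                      rec_strand = "+", syn_strand = "+"))
      contig <- paste0(fl1, lay$left, gapseq, lay$right, fl2)
      rec_start <- nchar(fl1) + 1L
      rec_end <- rec_start + nchar(rec_cds) - 1L
      syn_start <- rec_end + spec$gap + 1L
      syn_end <- syn_start + nchar(syn_cds) - 1L

      # planted primer-site coordinates (divergent layout only)
      fwd_ok <- .variant_compatible(spec$receptor_variant, fwd_coding, table, 4L)
      rev_ok <- .variant_compatible(spec$synthase_variant, rev_coding, table, 5L)
      if (spec$orientation == "divergent") {
        c1 <- 3L * (.receptor_motif_aa - 1L) + 1L; c2 <- 3L * (.receptor_motif_aa + 8L)
        d1 <- 3L * (.synthase_motif_aa - 1L) + 1L; d2 <- 3L * (.synthase_motif_aa + 6L)
        fwd_site_start <- rec_end - c2 + 1L
        fwd_site_end <- rec_end - c1 + 1L
        rev_site_start <- syn_start + d1 - 1L
        rev_site_end <- syn_start + d2 - 1L
        expected <- if (fwd_ok && rev_ok) rev_site_end - fwd_site_start + 1L else NA_integer_
      } else {
        fwd_site_start <- NA_integer_; fwd_site_end <- NA_integer_
        rev_site_start <- NA_integer_; rev_site_end <- NA_integer_
        expected <- NA_integer_
      }

      feats <- tibble(
        contig_id = contig_id,
        start = c(rec_start, syn_start), end = c(rec_end, syn_end),
        strand = c(lay$rec_strand, lay$syn_strand),
        locus_tag = paste0(contig_id, c("_rec", "_syn")),
        protein = c(rec, syn))
      genome <- genome_record(contig_id, contig, feats, source_path = NA_character_)

      # reject assemblies with spurious primer sites beyond the planted ones
      n_fwd <- nrow(match_primer(fwd_primer, contig))
      n_rev <- nrow(match_primer(rev_primer, contig))
      exp_fwd <- as.integer(fwd_ok); exp_rev <- as.integer(rev_ok)
      if (n_fwd == exp_fwd && n_rev == exp_rev) {
        truth <- tibble(
          contig_id = contig_id, orientation = spec$orientation, gap = spec$gap,
          receptor_start = rec_start, receptor_end = rec_end,
          receptor_strand = lay$rec_strand,
          synthase_start = syn_start, synthase_end = syn_end,
          synthase_strand = lay$syn_strand,
          receptor_variant = spec$receptor_variant,
          synthase_variant = spec$synthase_variant,
          fwd_site_start = fwd_site_start, fwd_site_end = fwd_site_end,
          rev_site_start = rev_site_start, rev_site_end = rev_site_end,
          expected_amplicon = expected,
          are_start = if (!is.null(spec$are)) rec_end + spec$are$offset else NA_integer_,
          are_consensus = if (!is.null(spec$are)) toupper(spec$are$consensus) else NA_character_,
          identity = spec$identity, seed = spec$seed)
        return(list(genome = genome, truth = truth))
      }
    }
    stop("could not assemble a locus free of spurious primer sites", call. = FALSE)
  })
}

# does a motif variant carry at least one codon choice fully compatible with
# the primer's coding-sense pattern at every motif position?
.variant_compatible <- function(variant, coding_pattern, table, motif_len) {
  res <- strsplit(variant, "")[[1]]
  all(vapply(seq_len(motif_len), function(i) {
    pat <- substr(coding_pattern, 3L * i - 2L, 3L * i)
    length(intersect(codons_for(res[i], table), expand_degenerate(pat))) > 0L
  }, logical(1)))
}

#' Default cohort frequencies emulating the screened corpus
#'
#' Orientation and binding-site variant frequencies matching the published
#' corpus proportions (90.2% divergent; YFHx-class receptor variants and
#' ETxRx-class synthase variants at their printed relative rates).
#'
#' @return list with `orientation`, `receptor`, `synthase` named probability
#'   vectors.
#' @export
cohort_defaults <- function() {
  list(
    orientation = c(divergent = 0.902, convergent = 0.05, tandem = 0.048),
    receptor = c(YFHF = 0.8620, YFHY = 0.0731, HFHF = 0.0437, YHHF = 0.0132,
                 YLHF = 0.0030, HFHY = 0.0050),
    synthase = c(ETLRQ = 0.3500, ETIRQ = 0.2000, ETVRQ = 0.1535, ETLRG = 0.0386,
                 ESVRQ = 0.1076, EAVRQ = 0.1503))
}

#' Generate a cohort of synthetic gene-pair loci
#'
#' Samples orientation and motif variants per locus from the given
#' frequencies (defaults emulate the screened corpus, see
#' [cohort_defaults()]), generates each locus with [generate_pair_locus()],
#' and returns the genomes with a ground-truth table. Deterministic given
#' `seed`.
#'
#' @param n number of loci (> 0).
#' @param orientation_mix named probabilities over orientation classes
#'   (must sum to 1).
#' @param receptor_freqs,synthase_freqs named variant probabilities (sum 1).
#' @param gap_range intergenic gap sampling range in bp.
#' @param identity_range protein identity sampling range.
#' @param are optional `list(consensus=, offset=)` planted in every
#'   divergent locus (offset must fit the smallest gap).
#' @param seed cohort seed.
#' @return list with `genomes` (list of [genome_record()]) and `truth`
#'   (tibble, one row per locus).
#' @export
generate_cohort <- function(n, orientation_mix = cohort_defaults()$orientation,
                            receptor_freqs = cohort_defaults()$receptor,
                            synthase_freqs = cohort_defaults()$synthase,
                            gap_range = c(80L, 550L),
                            identity_range = c(0.75, 0.95),
                            are = NULL, seed = 1L) {
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  stopifnot(abs(sum(orientation_mix) - 1) < 1e-9,
            abs(sum(receptor_freqs) - 1) < 1e-9,
            abs(sum(synthase_freqs) - 1) < 1e-9)
  draws <- .with_seed(seed, {
    tibble(
      orientation = sample(names(orientation_mix), n, TRUE, orientation_mix),
      receptor_variant = sample(names(receptor_freqs), n, TRUE, receptor_freqs),
      synthase_variant = sample(names(synthase_freqs), n, TRUE, synthase_freqs),
      gap = sample(seq.int(gap_range[1], gap_range[2]), n, TRUE),
      identity = round(stats::runif(n, identity_range[1], identity_range[2]), 3),
      locus_seed = sample.int(1e6L, n))
  })
  table <- codon_usage_table()
  out <- purrr::map(seq_len(n), function(i) {
    sp <- plant_spec(orientation = draws$orientation[i], gap = draws$gap[i],
                     receptor_variant = draws$receptor_variant[i],
                     synthase_variant = draws$synthase_variant[i],
                     are = if (draws$orientation[i] == "divergent") are else NULL,
                     identity = draws$identity[i], seed = draws$locus_seed[i])
    generate_pair_locus(sp, table, contig_id = sprintf("synthfix_%03d", i))
  })
  list(genomes = purrr::map(out, "genome"),
       truth = purrr::map_dfr(out, "truth"))
}

#' Plant-spec panel mimicking the screened strain set
#'
#' Eight divergent loci with the binding-site variant combinations and
#' expected product sizes of the strains the screen was validated on
#' (including the incompatible HHHF and YHHF receptor variants that yield no
#' product at zero mismatches).
#'
#' @return named list of [plant_spec()] objects.
#' @export
fixture_strain_panel <- function() {
  list(
    plasmid_mmf   = plant_spec(receptor_variant = "YFHF", synthase_variant = "ETIRQ",
                               target_amplicon = 600L, seed = 9001L),
    isolate_314   = plant_spec(receptor_variant = "YFHF", synthase_variant = "EAVRQ",
                               target_amplicon = 516L, seed = 9002L),
    isolate_2III1 = plant_spec(receptor_variant = "HHHF", synthase_variant = "EAIRQ",
                               target_amplicon = 627L, seed = 9003L),
    isolate_0IV2  = plant_spec(receptor_variant = "YHHF", synthase_variant = "ESVRQ",
                               target_amplicon = 597L, seed = 9004L),
    venezuelae    = plant_spec(receptor_variant = "YFHY", synthase_variant = "ETVRQ",
                               target_amplicon = 590L, seed = 9005L),
    avermitilis   = plant_spec(receptor_variant = "YFHF", synthase_variant = "ETLRQ",
                               target_amplicon = 697L, seed = 9006L),
    coelicolor    = plant_spec(receptor_variant = "YFHF", synthase_variant = "ETLRQ",
                               target_amplicon = 513L, seed = 9007L),
    lividans      = plant_spec(receptor_variant = "YFHF", synthase_variant = "ETLRQ",
                               target_amplicon = 533L, seed = 9008L))
}

#' Generate sequences with a planted (noisy) motif for EM benchmarking
#'
#' Each sequence is order-0 background at the given GC with one planted copy
#' of the consensus, each motif position flipped to a random other base with
#' probability `noise`; a configurable fraction of copies is planted on the
#' reverse strand. Ground truth records offsets and strands.
#'
#' @param n number of sequences.
#' @param len sequence length.
#' @param consensus motif string (default: bundled 18 bp palindromic
#'   operator).
#' @param noise per-position substitution probability.
#' @param rc_fraction fraction of copies planted on the reverse strand.
#' @param gc background GC content.
#' @param seed integer seed.
#' @return list with `seqs` (named character) and `truth` tibble (seq_id,
#'   offset, strand).
#' @export
generate_are_set <- function(n = 7L, len = 500L, consensus = .default_are(),
                             noise = 0.1, rc_fraction = 0, gc = 0.7, seed = 1L) {
  w <- nchar(consensus)
  .with_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      bg <- .gc_background(len)
      motif <- strsplit(toupper(consensus), "")[[1]]
      flip <- stats::runif(w) < noise
      motif[flip] <- vapply(motif[flip], function(b) sample(setdiff(.dna4, b), 1L), "")
      m <- paste(motif, collapse = "")
      strand <- if (stats::runif(1) < rc_fraction) "-" else "+"
      if (strand == "-") m <- revcomp(m)
      off <- sample.int(len - w + 1L, 1L)
      substr(bg, off, off + w - 1L) <- m
      list(seq = bg, truth = tibble(seq_id = sprintf("are_%02d", i),
                                    offset = off, strand = strand))
    })
    seqs <- stats::setNames(purrr::map_chr(rows, "seq"),
                            purrr::map_chr(rows, ~ .x$truth$seq_id))
    list(seqs = seqs, truth = purrr::map_dfr(rows, "truth"))
  })
}

# ---- fixture writers --------------------------------------------------------

#' Write genomes as a GenBank flat file
#'
#' Minimal deterministic GenBank output (LOCUS, CDS features with
#' `/locus_tag` and `/translation`, ORIGIN), one record per contig.
#'
#' @param genomes a [genome_record()] or list of them.
#' @param path output path.
#' @export
write_genome_genbank <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   UNA 01-JAN-1980",
                       g$contig_id, nchar(g$sequence)), con)
    writeLines(sprintf("DEFINITION  synthetic fixture contig %s.", g$contig_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    if (nrow(g$features) > 0L) {
      for (i in seq_len(nrow(g$features))) {
        f <- g$features[i, ]
        loc <- sprintf("%d..%d", f$start, f$end)
        if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
        writeLines(sprintf("     CDS             %s", loc), con)
        writeLines(sprintf('                     /locus_tag="%s"', f$locus_tag), con)
        tr <- f$protein
        chunks <- substring(tr, seq(1, nchar(tr), 44), pmin(seq(1, nchar(tr), 44) + 43, nchar(tr)))
        writeLines(sprintf('                     /translation="%s"',
                           paste(chunks, collapse = "\n                     ")), con)
      }
    }
    writeLines("ORIGIN", con)
    s <- tolower(g$sequence)
    starts <- seq(1, nchar(s), by = 60)
    for (st in starts) {
      chunk <- substr(s, st, min(st + 59, nchar(s)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
      writeLines(sprintf("%9d %s", st, paste(tens, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write genomes as GFF3 + FASTA
#'
#' @param genomes a [genome_record()] or list of them.
#' @param gff_path,fasta_path output paths.
#' @export
write_genome_gff3 <- function(genomes, gff_path, fasta_path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  lines <- "##gff-version 3"
  for (g in genomes) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", g$contig_id, nchar(g$sequence)))
    if (nrow(g$features) > 0L) {
      lines <- c(lines, sprintf(
        "%s\tgblscreen\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s",
        g$features$contig_id, g$features$start, g$features$end,
        g$features$strand, g$features$locus_tag, g$features$locus_tag))
    }
  }
  writeLines(lines, gff_path)
  seqs <- stats::setNames(vapply(genomes, function(g) g$sequence, ""),
                          vapply(genomes, function(g) g$contig_id, ""))
  write_fasta(seqs, fasta_path)
  invisible(gff_path)
}

#' Write a fixture bundle (GenBank + GFF3 + FASTA + truth TSV)
#'
#' @param cohort list with `genomes` and `truth` (as from
#'   [generate_cohort()] or a single [generate_pair_locus()] result wrapped
#'   accordingly).
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return the directory, invisibly.
#' @export
write_fixture_bundle <- function(cohort, dir, prefix = "fixtures") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genome_genbank(cohort$genomes, file.path(dir, paste0(prefix, ".gbk")))
  write_genome_gff3(cohort$genomes, file.path(dir, paste0(prefix, ".gff3")),
                    file.path(dir, paste0(prefix, ".fasta")))
  readr::write_tsv(cohort$truth, file.path(dir, paste0(prefix, "_truth.tsv")))
  invisible(dir)
}
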
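# End-to-end screen orchestration: genomes -> homologue pairs -> orientation
# census -> motif-variant table -> primers -> in-silico PCR -> operator motif.

#' Screen configuration
#'
#' Defaults follow the screen's stated parameters: homology E-value below
#' 0.02, maximum intergenic distance 600 bp, divergent orientation filter,
#' and operator motif widths 15-30.
#'
#' @param receptor_query,synthase_query query protein strings (defaults:
#'   the bundled synthetic stand-in queries).
#' @param evalue_max homology threshold.
#' @param max_intergenic maximum inter-CDS gap in bp.
#' @param orientation_filter orientation consumed by the primer stage.
#' @param motif_window receptor/synthase anchor window lengths.
#' @param max_mismatch,three_prime_exact,min_size,max_size PCR matching
#'   parameters.
#' @param are_wmin,are_wmax operator motif width range.
#' @param are_width_shuffles shuffles per width for width calibration.
#' @param are_max_seqs cap on the number of intergenic regions fed to motif
#'   discovery (seed enumeration is quadratic in total input length; the
#'   wet-lab stage this emulates ran on a handful of Sanger products).
#' @param seed screen seed.
#' @param out_dir output directory (NULL = no files written).
#' @return list of class `screen_config`.
#' @export
screen_config <- function(receptor_query = synthetic_queries()$receptor,
                          synthase_query = synthetic_queries()$synthase,
                          evalue_max = 0.02, max_intergenic = 600L,
                          orientation_filter = "divergent",
                          motif_window = c(receptor = 4L, synthase = 5L),
                          max_mismatch = 0L, three_prime_exact = 3L,
                          min_size = 100L, max_size = 3000L,
                          are_wmin = 15L, are_wmax = 30L,
                          are_width_shuffles = 5L, are_max_seqs = 10L,
                          seed = 1L, out_dir = NULL) {
  structure(list(receptor_query = receptor_query, synthase_query = synthase_query,
                 evalue_max = evalue_max, max_intergenic = as.integer(max_intergenic),
                 orientation_filter = orientation_filter,
                 motif_window = motif_window,
                 max_mismatch = as.integer(max_mismatch),
                 three_prime_exact = as.integer(three_prime_exact),
                 min_size = as.integer(min_size), max_size = as.integer(max_size),
                 are_wmin = as.integer(are_wmin), are_wmax = as.integer(are_wmax),
                 are_width_shuffles = as.integer(are_width_shuffles),
                 are_max_seqs = as.integer(are_max_seqs),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "screen_config")
}

.stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the end-to-end screen
#'
#' Stages: (1) load genomes; (2) find receptor and synthase homologues in
#' all CDS translations; (3) pair collocated hits and take the orientation
#' census; (4) align the motif windows of filtered pairs and tabulate
#' binding-site variants; (5) design the degenerate primer pair from the
#' bundled policies; (6) predict amplicons and per-pair priming classes per
#' genome; (7) discover the shared operator motif in the intergenic regions
#' of divergent pairs (when at least 3 long enough). Intermediates are
#' persisted as TSV/FASTA under `config$out_dir` when set. Deterministic
#' given `config$seed`.
#'
#' @param config a [screen_config()].
#' @param genomes list of [genome_record()] objects, or file paths readable
#'   by [read_annotated_genome()].
#' @return list of class `screen_report`: genomes, hits, pairs, census,
#'   variant_counts, efficacy, primers (tidy tibble), amplicons,
#'   prime_classes, are_model.
#' @export
run_screen <- function(config, genomes) {
  stopifnot(inherits(config, "screen_config"), length(genomes) >= 1L)
  if (is.character(genomes)) {
    genomes <- unlist(lapply(genomes, read_annotated_genome), recursive = FALSE)
  }
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  table <- codon_usage_table()

  .stage_log("homology", "searching %d genomes", length(genomes))
  proteome <- cds_features(genomes)
  rec_hits <- find_homologs(proteome, config$receptor_query, "receptor",
                            evalue_max = config$evalue_max)
  syn_hits <- find_homologs(proteome, config$synthase_query, "synthase",
                            evalue_max = config$evalue_max)
  .stage_log("homology", "%d receptor, %d synthase hits", nrow(rec_hits), nrow(syn_hits))

  pairs <- pair_colocated(syn_hits, rec_hits, max_intergenic = config$max_intergenic)
  census <- orientation_census(pairs)
  .stage_log("pairing", "%d pairs (%s)", nrow(pairs),
             paste(sprintf("%s=%d", census$orientation, census$n), collapse = ", "))

  kept <- pairs[pairs$orientation %in% config$orientation_filter, , drop = FALSE]

  # motif-variant table from the alignment columns of the anchor windows
  variant_counts <- NULL; efficacy <- NULL
  rec_vars <- character(0); syn_vars <- character(0)
  if (nrow(kept) > 0L) {
    rec_vars <- .window_variants_for(kept$receptor_protein, config$receptor_query,
                                     .receptor_motif_aa, 4L)
    syn_vars <- .window_variants_for(kept$synthase_protein, config$synthase_query,
                                     .synthase_motif_aa, 5L)
    rec_patterns <- c("YFHF", "YFHx", "YxHF", "xFHF", "YHHF", "HHHF")
    syn_patterns <- c("ETxRQ", "ETxRx", "ESxRQ")
    variant_counts <- dplyr::bind_rows(
      dplyr::mutate(count_motif_patterns(rec_vars, rec_patterns), target = "receptor"),
      dplyr::mutate(count_motif_patterns(syn_vars, syn_patterns), target = "synthase"))
    efficacy <- estimate_amplifiable(rec_vars, syn_vars, "YFHx", "ETxRx")
    .stage_log("motifs", "amplifiable %d/%d (%.1f%%)",
               efficacy$n_amplifiable, efficacy$n_pairs, efficacy$percent)
  }

  pol <- scb_policies()
  primers <- list(
    scb_F = design_primer(pol$scb_F$context, pol$scb_F$policy, table,
                          role = "receptor", name = "scb_F", motif_len = 4L),
    scb_R = design_primer(pol$scb_R$context, pol$scb_R$policy, table,
                          role = "synthase", name = "scb_R", motif_len = 5L))
  .stage_log("primers", "scb_F %s / scb_R %s",
             primers$scb_F$sequence, primers$scb_R$sequence)

  amplicons <- purrr::map_dfr(genomes, function(g) {
    predict_amplicons(primers$scb_F, primers$scb_R, g$sequence,
                      min_size = config$min_size, max_size = config$max_size,
                      max_mismatch = config$max_mismatch,
                      three_prime_exact = config$three_prime_exact,
                      contig_id = g$contig_id)
  })
  .stage_log("insilico-pcr", "%d predicted amplicons", nrow(amplicons))

  prime_classes <- NULL
  if (nrow(kept) > 0L) {
    prime_classes <- tibble(
      contig_id = kept$contig_id,
      receptor_variant = rec_vars, synthase_variant = syn_vars,
      receptor_class = vapply(rec_vars, function(v)
        as.character(classify_priming(v, "YFHF", primers$scb_F, table)), "",
        USE.NAMES = FALSE),
      synthase_class = vapply(syn_vars, function(v)
        as.character(classify_priming(v, "ETxRQ", primers$scb_R, table)), "",
        USE.NAMES = FALSE))
  }

  are_model <- NULL
  if (nrow(kept) > 0L) {
    div <- kept[kept$orientation == "divergent", , drop = FALSE]
    by_id <- stats::setNames(genomes, vapply(genomes, function(g) g$contig_id, ""))
    igs <- vapply(seq_len(nrow(div)), function(i)
      intergenic_sequence(div[i, ], by_id[[div$contig_id[i]]]), "")
    igs <- igs[nchar(igs) >= config$are_wmax]
    if (length(igs) > config$are_max_seqs) igs <- igs[seq_len(config$are_max_seqs)]
    if (length(igs) >= 3L) {
      .stage_log("are", "EM motif discovery over %d intergenic regions", length(igs))
      are_model <- discover_motif(igs, wmin = config$are_wmin, wmax = config$are_wmax,
                                  seed = config$seed,
                                  width_shuffles = config$are_width_shuffles)
    }
  }

  report <- structure(list(
    genomes = genomes, receptor_hits = rec_hits, synthase_hits = syn_hits,
    pairs = pairs, census = census, variant_counts = variant_counts,
    efficacy = efficacy,
    primers = dplyr::bind_rows(lapply(primers, tidy)),
    primer_objects = primers,
    amplicons = amplicons, prime_classes = prime_classes,
    are_model = are_model, config = config), class = "screen_report")
  if (!is.null(config$out_dir)) .persist_report(report, config$out_dir)
  report
}

# read the anchor-window residues of each homologue protein by star-aligning
# it to the query and taking the query-anchored columns
.window_variants_for <- function(proteins, query, motif_aa, win_len) {
  vapply(proteins, function(p) {
    msa <- align_homologs(c(query = query, hit = p), reference = "query")
    cols <- .query_columns(msa)
    idx <- cols[motif_aa:(motif_aa + win_len - 1L)]
    hit_row <- strsplit(unclass(msa)[["hit"]], "")[[1]]
    paste(hit_row[idx], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# alignment column of each reference residue
.query_columns <- function(msa) {
  ref_id <- attr(msa, "reference")
  ref_row <- strsplit(unclass(msa)[[ref_id]], "")[[1]]
  which(ref_row != "-")
}

.persist_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(report$pairs, file.path(dir, "pairs.tsv"))
  readr::write_tsv(report$census, file.path(dir, "orientation_census.tsv"))
  if (!is.null(report$variant_counts)) {
    readr::write_tsv(report$variant_counts, file.path(dir, "variant_counts.tsv"))
  }
  if (!is.null(report$efficacy)) {
    readr::write_tsv(report$efficacy, file.path(dir, "efficacy.tsv"))
  }
  readr::write_tsv(report$primers, file.path(dir, "primers.tsv"))
  readr::write_tsv(report$amplicons, file.path(dir, "amplicons.tsv"))
  if (!is.null(report$prime_classes)) {
    readr::write_tsv(report$prime_classes, file.path(dir, "prime_classes.tsv"))
  }
  div <- report$pairs[report$pairs$orientation == "divergent", , drop = FALSE]
  if (nrow(div) > 0L) {
    by_id <- stats::setNames(report$genomes,
                             vapply(report$genomes, function(g) g$contig_id, ""))
    igs <- vapply(seq_len(nrow(div)), function(i)
      intergenic_sequence(div[i, ], by_id[[div$contig_id[i]]]), "")
    keep <- nchar(igs) > 0L
    if (any(keep)) {
      write_fasta(stats::setNames(igs[keep], div$contig_id[keep]),
                  file.path(dir, "intergenic.fasta"))
    }
  }
  if (!is.null(report$are_model)) {
    write_motif_meme(report$are_model, file.path(dir, "are_motif.meme"))
    readr::write_tsv(report$are_model$sites, file.path(dir, "are_sites.tsv"))
  }
  invisible(dir)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  cat(sprintf("  genomes: %d | pairs: %d | amplicons: %d\n",
              length(x$genomes), nrow(x$pairs), nrow(x$amplicons)))
  cat(sprintf("  census: %s\n",
              paste(sprintf("%s=%d", x$census$orientation, x$census$n), collapse = ", ")))
  if (!is.null(x$efficacy)) {
    cat(sprintf("  amplifiable: %d/%d (%.1f%%)\n", x$efficacy$n_amplifiable,
                x$efficacy$n_pairs, x$efficacy$percent))
  }
  if (!is.null(x$are_model)) {
    cat(sprintf("  operator motif: width %d, palindromicity %.2f\n",
                x$are_model$width, x$are_model$palindromicity))
  }
  invisible(x)
}

#' @rdname tidy.degenerate_primer
#' @exportS3Method generics::glance
glance.screen_report <- function(x, ...) {
  tibble(n_genomes = length(x$genomes), n_pairs = nrow(x$pairs),
         n_divergent = x$census$n[x$census$orientation == "divergent"],
         n_amplicons = nrow(x$amplicons),
         percent_amplifiable = if (is.null(x$efficacy)) NA_real_ else x$efficacy$percent,
         are_width = if (is.null(x$are_model)) NA_integer_ else x$are_model$width,
         are_palindromicity = if (is.null(x$are_model)) NA_real_ else
           x$are_model$palindromicity)
}
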
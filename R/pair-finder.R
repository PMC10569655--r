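# Homologue search and collocated-pair detection: the desk-scale equivalent of
# a cblaster screen for synthase/receptor gene pairs.

# Ungapped Karlin-Altschul parameters for BLOSUM62, applied to gapped local
# scores as a deliberate approximation (threshold parity with BLAST is not
# claimed; tests use large score margins).
.ka_lambda <- 0.318
.ka_K <- 0.13

#' Find homologues of a query protein in a proteome
#'
#' Local (Smith-Waterman) alignment with affine gaps and BLOSUM62 scoring
#' against every CDS translation, with an E-value computed from the
#' Karlin-Altschul formula `E = K m n exp(-lambda S)` on an effective search
#' space of query length x summed proteome length. Hits overlapping the same
#' locus are deduplicated by best score.
#'
#' @param proteome tibble of CDS features (see [cds_features()]) with a
#'   `protein` column.
#' @param query amino-acid string (length >= 20).
#' @param query_id label recorded on the hits.
#' @param evalue_max report only hits with expectation below this (default
#'   0.02, the screen's homology threshold).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return tibble of hits sorted by descending score: query_id, locus_tag,
#'   contig_id, start, end, strand, protein, score, bits, evalue, identity.
#' @export
find_homologs <- function(proteome, query, query_id = "query", evalue_max = 0.02,
                          gap_opening = 11, gap_extension = 1) {
  stopifnot(nrow(proteome) >= 1L, nchar(query) >= 20L)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", toupper(query))) {
    stop("query contains non-amino-acid characters", call. = FALSE)
  }
  query <- toupper(query)
  subjects <- proteome$protein
  ok <- !is.na(subjects) & nzchar(subjects)
  n_space <- sum(nchar(subjects[ok]))
  m <- nchar(query)
  rows <- purrr::map(which(ok), function(i) {
    subj <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", toupper(subjects[i]))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(subj),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension)
    s <- Biostrings::score(aln)
    ev <- .ka_K * m * n_space * exp(-.ka_lambda * s)
    if (ev >= evalue_max) return(NULL)
    dplyr::bind_cols(proteome[i, ], tibble(
      query_id = query_id,
      score = s,
      bits = (.ka_lambda * s - log(.ka_K)) / log(2),
      evalue = ev,
      identity = Biostrings::pid(aln, type = "PID1") / 100))
  })
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits) == 0L) {
    return(tibble(contig_id = character(), start = integer(), end = integer(),
                  strand = character(), locus_tag = character(), protein = character(),
                  query_id = character(), score = double(), bits = double(),
                  evalue = double(), identity = double()))
  }
  hits <- hits %>%
    dplyr::group_by(.data$contig_id, .data$start, .data$end) %>%
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(dplyr::desc(.data$score))
  hits
}

# gap in bp between the nearest boundaries of two 1-based inclusive intervals;
# overlapping intervals give 0
.interval_gap <- function(s1, e1, s2, e2) {
  pmax(pmax(s1, s2) - pmin(e1, e2) - 1L, 0L)
}

.orient_class <- function(left_strand, right_strand) {
  dplyr::case_when(
    left_strand == "-" & right_strand == "+" ~ "divergent",
    left_strand == "+" & right_strand == "-" ~ "convergent",
    TRUE ~ "tandem")
}

#' Pair collocated synthase and receptor hits
#'
#' One pair is emitted for every (synthase, receptor) hit combination on the
#' same contig whose inter-CDS gap (bp between the two closest CDS
#' boundaries, strand-agnostic) is at most `max_intergenic`; overlapping CDS
#' count as gap 0. Orientation is classified from the strands of the left and
#' right feature by coordinate: left on `-` and right on `+` is divergent
#' (back-to-back, 5' ends flanking the shared gap); the mirror case is
#' convergent; same strand is tandem. Pairs whose CDS overlap by more than
#' `overlap_tolerance` bp are flagged orientation `"ambiguous"`.
#'
#' @param synthase_hits,receptor_hits hit tibbles from [find_homologs()].
#' @param max_intergenic maximum allowed gap in bp (default 600).
#' @param overlap_tolerance maximum CDS overlap before the pair is flagged
#'   ambiguous (default 30 bp).
#' @return tibble of gene pairs with gap, orientation and the intergenic
#'   interval (1-based inclusive; zero-width encoded as start > end).
#' @export
pair_colocated <- function(synthase_hits, receptor_hits, max_intergenic = 600L,
                           overlap_tolerance = 30L) {
  empty <- tibble(contig_id = character(),
                  synthase_locus = character(), synthase_start = integer(),
                  synthase_end = integer(), synthase_strand = character(),
                  synthase_protein = character(),
                  receptor_locus = character(), receptor_start = integer(),
                  receptor_end = integer(), receptor_strand = character(),
                  receptor_protein = character(),
                  gap = integer(), orientation = character(),
                  intergenic_start = integer(), intergenic_end = integer())
  if (nrow(synthase_hits) == 0L || nrow(receptor_hits) == 0L) return(empty)
  syn <- synthase_hits %>%
    dplyr::select(contig_id = "contig_id", synthase_locus = "locus_tag",
                  synthase_start = "start", synthase_end = "end",
                  synthase_strand = "strand", synthase_protein = "protein")
  rec <- receptor_hits %>%
    dplyr::select(contig_id = "contig_id", receptor_locus = "locus_tag",
                  receptor_start = "start", receptor_end = "end",
                  receptor_strand = "strand", receptor_protein = "protein")
  pairs <- dplyr::inner_join(syn, rec, by = "contig_id", relationship = "many-to-many")
  if (nrow(pairs) == 0L) return(empty)
  pairs <- pairs %>%
    dplyr::filter(!(.data$synthase_start == .data$receptor_start &
                      .data$synthase_end == .data$receptor_end)) %>%
    dplyr::mutate(
      gap = .interval_gap(.data$synthase_start, .data$synthase_end,
                          .data$receptor_start, .data$receptor_end),
      overlap = pmax(pmin(.data$synthase_end, .data$receptor_end) -
                       pmax(.data$synthase_start, .data$receptor_start) + 1L, 0L),
      left_strand = ifelse(.data$synthase_start <= .data$receptor_start,
                           .data$synthase_strand, .data$receptor_strand),
      right_strand = ifelse(.data$synthase_start <= .data$receptor_start,
                            .data$receptor_strand, .data$synthase_strand),
      orientation = ifelse(.data$overlap > overlap_tolerance, "ambiguous",
                           .orient_class(.data$left_strand, .data$right_strand)),
      intergenic_start = pmin(.data$synthase_end, .data$receptor_end) + 1L,
      intergenic_end = pmax(.data$synthase_start, .data$receptor_start) - 1L) %>%
    dplyr::filter(.data$gap <= max_intergenic) %>%
    dplyr::select(-"overlap", -"left_strand", -"right_strand") %>%
    dplyr::arrange(.data$contig_id, .data$synthase_start, .data$receptor_start)
  pairs
}

#' Classify pair orientation
#'
#' Adds (or recomputes) the `orientation` column of a pair tibble from the
#' strands of the coordinate-left and -right CDS.
#'
#' @param pairs pair tibble from [pair_colocated()].
#' @return the tibble with `orientation` in
#'   `{divergent, convergent, tandem}`.
#' @export
classify_orientation <- function(pairs) {
  dplyr::mutate(pairs,
    orientation = .orient_class(
      ifelse(.data$synthase_start <= .data$receptor_start,
             .data$synthase_strand, .data$receptor_strand),
      ifelse(.data$synthase_start <= .data$receptor_start,
             .data$receptor_strand, .data$synthase_strand)))
}

#' Count pairs per orientation class
#'
#' @param pairs pair tibble.
#' @return tibble with one row per orientation class (divergent, convergent,
#'   tandem) and the count of pairs; counts always sum to the number of
#'   unambiguous pairs.
#' @export
orientation_census <- function(pairs) {
  lv <- c("divergent", "convergent", "tandem")
  counted <- pairs %>%
    dplyr::filter(.data$orientation %in% lv) %>%
    dplyr::count(orientation = factor(.data$orientation, levels = lv),
                 .drop = FALSE, name = "n")
  tidyr::complete(counted, orientation = factor(lv, levels = lv),
                  fill = list(n = 0L)) %>%
    dplyr::mutate(orientation = as.character(.data$orientation)) %>%
    dplyr::arrange(match(.data$orientation, lv))
}

#' Extract the intergenic sequence of a divergent pair
#'
#' Returns the plus-strand gap sequence between the two CDS. The shared
#' intergenic region carries the autoregulatory response element only for
#' divergent (back-to-back) pairs, so other orientations are an error.
#'
#' @param pair one-row pair tibble.
#' @param genome the [genome_record()] the pair lies on.
#' @return DNA string (possibly empty for overlapping CDS).
#' @export
intergenic_sequence <- function(pair, genome) {
  if (!identical(pair$orientation, "divergent")) {
    stop("intergenic regulatory region is defined only for divergent pairs",
         call. = FALSE)
  }
  if (pair$intergenic_end < pair$intergenic_start) return("")
  substr(genome$sequence, pair$intergenic_start, pair$intergenic_end)
}

#' Write a pair table as TSV
#' @param pairs pair tibble.
#' @param path output path.
#' @export
write_pairs_tsv <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}
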
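#' @useDynLib gblscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# IUPAC nucleotide code -> base set, and the reverse lookup (keys are sorted
# base strings). Built once at load from Biostrings' map so the two stay in sync.
.iupac_sets <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(x) strsplit(x, "")[[1]])
})
.iupac_lookup <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  key <- vapply(m, function(x) paste(sort(strsplit(x, "")[[1]]), collapse = ""), "")
  stats::setNames(names(m), key)
})

#' Validate an IUPAC DNA string
#'
#' @param seq character scalar.
#' @param what label used in error messages.
#' @return `seq`, invisibly, if valid.
#' @keywords internal
check_iupac <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% names(.iupac_sets))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC character '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement of an IUPAC DNA string
#'
#' Degenerate codes map to their complements (R<->Y, S<->S, W<->W, K<->M,
#' B<->V, D<->H, N<->N), so `revcomp()` is an involution on the full IUPAC
#' alphabet. Used to relate antisense degenerate primers to the coding strand.
#'
#' @param seq character vector of IUPAC DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("CCGCTCCTTGCTSGGRAARTGRAARTA")
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    check_iupac(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Merge concrete codons/strings into a minimal IUPAC cover
#'
#' Position-wise union of bases, encoded with the tightest ambiguity code.
#'
#' @param strings character vector of equal-length DNA strings.
#' @return single IUPAC string covering all inputs.
#' @export
iupac_merge <- function(strings) {
  stopifnot(length(strings) >= 1L)
  n <- unique(nchar(strings))
  if (length(n) != 1L) stop("strings must have equal length", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(strings), ""))
  out <- vapply(seq_len(n), function(j) {
    bases <- sort(unique(unlist(.iupac_sets[mat[, j]])))
    .iupac_lookup[[paste(bases, collapse = "")]]
  }, character(1))
  paste(out, collapse = "")
}

#' Per-position cardinality product of an IUPAC string
#'
#' @param seq IUPAC DNA string.
#' @return integer, the number of concrete sequences the string encodes.
#' @export
degeneracy <- function(seq) {
  check_iupac(seq)
  chars <- strsplit(toupper(seq), "")[[1]]
  prod(vapply(.iupac_sets[chars], length, integer(1)))
}

#' Expand a degenerate IUPAC string into its concrete sequences
#'
#' @param seq IUPAC DNA string.
#' @param cap refuse to expand beyond this many sequences.
#' @return character vector of concrete DNA strings over A/C/G/T.
#' @examples
#' expand_degenerate("TAY")
#' @export
expand_degenerate <- function(seq, cap = 10000L) {
  check_iupac(seq)
  d <- degeneracy(seq)
  if (d > cap) {
    stop(sprintf("expansion of '%s' requires %d sequences (cap %d)", seq, d, cap),
         call. = FALSE)
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  sets <- .iupac_sets[chars]
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out)
}

#' Translate a DNA string with the bacterial genetic code
#'
#' @param dna coding-sense DNA string, length divisible by 3.
#' @param table NCBI genetic code id (default 11, bacterial).
#' @param init_codon treat the first codon as an initiator (alternative
#'   initiation codons such as GTG then translate to M). Off by default so
#'   the function behaves as a plain codon-table lookup.
#' @return amino-acid string; stop codons become `*`.
#' @export
translate_dna <- function(dna, table = 11L, init_codon = FALSE) {
  check_iupac(dna)
  code <- Biostrings::getGeneticCode(as.character(table))
  as.character(Biostrings::translate(Biostrings::DNAString(toupper(dna)),
                                     genetic.code = code,
                                     no.init.codon = !init_codon,
                                     if.fuzzy.codon = "solve"))
}

#' Construct a genome record
#'
#' A `genome_record` holds one contig: its sequence and a tibble of CDS
#' features (1-based inclusive coordinates, strand `+`/`-`, locus tag and
#' protein translation).
#'
#' @param contig_id contig name.
#' @param sequence DNA string over A/C/G/T/N.
#' @param features tibble with columns contig_id, start, end, strand,
#'   locus_tag, protein.
#' @param source_path provenance path, if read from a file.
#' @return object of class `genome_record`.
#' @export
genome_record <- function(contig_id, sequence, features = NULL, source_path = NA_character_) {
  stopifnot(nchar(sequence) >= 1L)
  if (is.null(features)) {
    features <- tibble(contig_id = character(), start = integer(), end = integer(),
                       strand = character(), locus_tag = character(), protein = character())
  }
  features <- as_tibble(features)
  if (nrow(features) > 0L) {
    stopifnot(all(features$start >= 1L), all(features$end <= nchar(sequence)),
              all(features$start < features$end),
              all(features$strand %in% c("+", "-")))
  }
  structure(list(contig_id = contig_id, sequence = toupper(sequence),
                 features = features, source_path = source_path),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %d CDS\n",
              x$contig_id, nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

#' Translate a CDS feature from its genome
#'
#' Minus-strand features are reverse-complemented before translation; a
#' trailing stop codon is removed. An internal stop raises an error flagging a
#' likely pseudogene.
#'
#' @param feature one-row tibble (or list) with start, end, strand.
#' @param genome a [genome_record()].
#' @param table genetic code id (default 11).
#' @return amino-acid string.
#' @export
translate_cds <- function(feature, genome, table = 11L) {
  start <- feature$start; end <- feature$end
  if ((end - start + 1L) %% 3L != 0L) {
    stop(sprintf("CDS interval [%d,%d] length not divisible by 3", start, end),
         call. = FALSE)
  }
  dna <- substr(genome$sequence, start, end)
  if (identical(feature$strand, "-")) dna <- revcomp(dna)
  aa <- translate_dna(dna, table, init_codon = TRUE)
  aa <- sub("\\*$", "", aa)
  if (grepl("\\*", aa)) {
    stop(sprintf("internal stop codon in CDS [%d,%d] (%s): possible pseudogene",
                 start, end, feature$strand), call. = FALSE)
  }
  aa
}

# ---- GenBank flat file ------------------------------------------------------

.parse_gb_location <- function(loc, line_no) {
  loc <- gsub("[<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order", loc)) return(NULL) # compound locations skipped by caller
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
  if (length(m) != 3L) {
    stop(sprintf("GenBank parse error at line %d: unparseable location '%s'",
                 line_no, loc), call. = FALSE)
  }
  list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

.parse_genbank_record <- function(lines, offset, path) {
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus_line) == 0L) {
    stop(sprintf("GenBank parse error near line %d in '%s': missing LOCUS", offset, path),
         call. = FALSE)
  }
  contig_id <- strsplit(trimws(sub("^LOCUS\\s+", "", locus_line[1])), "\\s+")[[1]][1]

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) {
    stop(sprintf("GenBank parse error in record '%s': missing ORIGIN", contig_id),
         call. = FALSE)
  }
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_start <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_start) > 0L) {
    block <- lines[(feat_start[1] + 1L):(ori[1] - 1L)]
    # feature table entries start at column 6; qualifiers are indented further
    key_idx <- grep("^     \\S", block)
    for (k in seq_along(key_idx)) {
      i <- key_idx[k]
      j <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(block)
      header <- block[i]
      key <- trimws(substr(header, 1, 20))
      if (key != "CDS") next
      cont <- if (j > i) trimws(block[(i + 1L):j]) else character()
      body <- paste(c(trimws(substr(header, 22, nchar(header))), cont), collapse = "\n")
      # location = text up to first qualifier
      parts <- strsplit(body, "\n/")[[1]]
      loc_text <- gsub("[\n ]", "", parts[1])
      loc <- .parse_gb_location(loc_text, offset + feat_start[1] + i)
      if (is.null(loc)) {
        warning(sprintf("skipping compound-location CDS '%s' in %s", loc_text, contig_id))
        next
      }
      quals <- if (length(parts) > 1L) parts[-1] else character()
      getq <- function(name) {
        hit <- grep(paste0("^", name, "="), quals, value = TRUE)
        if (length(hit) == 0L) return(NA_character_)
        v <- sub(paste0("^", name, "="), "", hit[1])
        gsub('["\n ]', "", v)
      }
      feats[[length(feats) + 1L]] <- tibble(
        contig_id = contig_id, start = loc$start, end = loc$end, strand = loc$strand,
        locus_tag = getq("locus_tag"), protein = getq("translation"))
    }
  }
  features <- if (length(feats) > 0L) dplyr::bind_rows(feats) else NULL
  list(contig_id = contig_id, sequence = sequence, features = features)
}

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(list())
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- list()
  for (r in seq_along(ends)) {
    chunk <- lines[starts[r]:ends[r]]
    if (!any(grepl("^LOCUS", chunk))) next
    rec <- .parse_genbank_record(chunk, starts[r], path)
    out[[length(out) + 1L]] <- rec
  }
  out
}

# ---- GFF3 + FASTA -----------------------------------------------------------

read_gff3_fasta <- function(gff_path, fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(seqs) == 0L) return(list())
  gr <- rtracklayer::import(gff_path)
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  recs <- lapply(names(seqs), function(cid) {
    sel <- gr[as.character(GenomicRanges::seqnames(gr)) == cid]
    feats <- NULL
    if (length(sel) > 0L) {
      lt <- if (!is.null(sel$locus_tag)) as.character(sel$locus_tag) else
        if (!is.null(sel$ID)) as.character(sel$ID) else rep(NA_character_, length(sel))
      feats <- tibble(contig_id = cid,
                      start = GenomicRanges::start(sel),
                      end = GenomicRanges::end(sel),
                      strand = as.character(GenomicRanges::strand(sel)),
                      locus_tag = lt,
                      protein = NA_character_)
    }
    list(contig_id = cid, sequence = as.character(seqs[[cid]]), features = feats)
  })
  recs
}

#' Read an annotated genome
#'
#' Reads a GenBank flat file (single or multi-record) or a GFF3 + genomic
#' FASTA pair. Every CDS feature carries a protein translation: the
#' annotation's own `/translation` when present, else recomputed with the
#' bacterial genetic code (table 11). CDS with coordinates outside the contig
#' are skipped with a warning; annotated translations that disagree with the
#' recomputed one are kept but logged.
#'
#' @param path GenBank file, or GFF3 file when `format = "gff3"`.
#' @param format `"genbank"` or `"gff3"`.
#' @param fasta genomic FASTA path, required for `format = "gff3"`.
#' @return list of [genome_record()] objects (possibly empty).
#' @export
read_annotated_genome <- function(path, format = c("genbank", "gff3"), fasta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  raw <- if (format == "genbank") {
    read_genbank(path)
  } else {
    if (is.null(fasta)) stop("format 'gff3' requires a genomic FASTA via `fasta`", call. = FALSE)
    read_gff3_fasta(path, fasta)
  }
  lapply(raw, function(rec) {
    feats <- rec$features
    g <- genome_record(rec$contig_id, rec$sequence, NULL, source_path = path)
    if (is.null(feats) || nrow(feats) == 0L) return(g)
    keep <- feats$start >= 1L & feats$end <= nchar(rec$sequence) & feats$start < feats$end
    if (any(!keep)) {
      warning(sprintf("skipped %d CDS with out-of-contig coordinates in %s",
                      sum(!keep), rec$contig_id))
      feats <- feats[keep, , drop = FALSE]
    }
    feats$protein <- vapply(seq_len(nrow(feats)), function(i) {
      computed <- tryCatch(translate_cds(feats[i, ], g), error = function(e) NA_character_)
      annotated <- feats$protein[i]
      if (!is.na(annotated) && nzchar(annotated)) {
        if (!is.na(computed) && !identical(annotated, computed)) {
          message(sprintf("annotated translation of %s differs from recomputed; keeping annotation",
                          feats$locus_tag[i]))
        }
        annotated
      } else computed
    }, character(1))
    genome_record(rec$contig_id, rec$sequence, feats, source_path = path)
  })
}

#' Collect all CDS features of one or more genomes into a proteome tibble
#'
#' @param genomes a `genome_record` or list of them.
#' @return tibble of CDS features with a `genome` list-column index.
#' @export
cds_features <- function(genomes) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  dplyr::bind_rows(lapply(genomes, function(g) g$features))
}

#' Load the bundled high-GC Streptomyces codon usage table
#'
#' A representative Streptomyces coelicolor-style usage table (relative
#' synonymous codon frequencies per amino acid, summing to 1 within each
#' residue). Drives codon choice in back-translation and fixture generation.
#'
#' @param path optional path to an alternative TSV with columns aa, codon, freq.
#' @return tibble with columns aa, codon, freq, sorted by aa then
#'   descending freq.
#' @export
codon_usage_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "codon_usage_streptomyces.tsv", package = "gblscreen")
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    aa = readr::col_character(), codon = readr::col_character(),
    freq = readr::col_double()))
  sums <- tapply(tab$freq, tab$aa, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop(sprintf("codon frequencies for %s do not sum to 1",
                 paste(names(sums)[abs(sums - 1) > 1e-9], collapse = ",")), call. = FALSE)
  }
  if (!setequal(unique(tab$aa), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
    stop("codon usage table must cover all 20 amino acids", call. = FALSE)
  }
  dplyr::arrange(tab, .data$aa, dplyr::desc(.data$freq), .data$codon)
}

#' Codons of an amino acid, optionally restricted to the top-n by usage
#'
#' @param aa single amino-acid letter.
#' @param table codon usage table tibble.
#' @param top keep only the `top` most frequent codons (NULL = all).
#' @return character vector of codons, most frequent first.
#' @export
codons_for <- function(aa, table, top = NULL) {
  rows <- table[table$aa == aa, , drop = FALSE]
  if (nrow(rows) == 0L) stop(sprintf("no codons for residue '%s'", aa), call. = FALSE)
  cods <- rows$codon[order(-rows$freq, rows$codon)]
  if (!is.null(top)) cods <- utils::head(cods, top)
  cods
}

# ---- FASTA writing ----------------------------------------------------------

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
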
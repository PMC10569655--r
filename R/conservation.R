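# Conservation profiling of homologue protein sets: star alignment around a
# reference, per-column information content, and anchor-motif window
# selection for degenerate primer design.

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Star-align homologues around a reference sequence
#'
#' Every sequence is globally aligned to the reference with affine gaps and
#' BLOSUM62, and the pairwise alignments are merged on reference coordinates
#' (insertions relative to the reference open shared gap columns). The
#' reference row keeps one column for each of its residues. Star alignment is
#' sufficient for the column statistics this package consumes; it is not a
#' full progressive MSA.
#'
#' @param seqs named character vector of amino-acid sequences (>= 2).
#' @param reference name (or index) of the reference sequence.
#' @return object of class `protein_msa`: named character vector of aligned
#'   rows (gap `-`), with attribute `reference`.
#' @export
align_homologs <- function(seqs, reference = 1L) {
  stopifnot(length(seqs) >= 2L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- vapply(seqs, toupper, "")
  bad <- vapply(seqs, function(s) grepl("[^ACDEFGHIKLMNPQRSTVWYX]", s), logical(1))
  if (any(bad)) {
    stop(sprintf("invalid characters in sequence(s): %s",
                 paste(names(seqs)[bad], collapse = ",")), call. = FALSE)
  }
  ref_id <- if (is.character(reference)) reference else names(seqs)[reference]
  stopifnot(ref_id %in% names(seqs))
  ref <- seqs[[ref_id]]
  lr <- nchar(ref)
  others <- setdiff(names(seqs), ref_id)

  # per sequence: residue aligned to each reference column (or '-'), plus
  # insertion strings keyed by the reference position they follow (0..lr)
  aligned_to_ref <- list()
  insertions <- list()
  for (id in others) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[id]]), Biostrings::AAString(ref),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    res <- character(lr)
    ins <- rep("", lr + 1L)
    rpos <- 0L
    for (k in seq_along(s)) {
      if (s[k] == "-") {
        ins[rpos + 1L] <- paste0(ins[rpos + 1L], p[k])
      } else {
        rpos <- rpos + 1L
        res[rpos] <- p[k]
      }
    }
    aligned_to_ref[[id]] <- res
    insertions[[id]] <- ins
  }
  slot_w <- rep(0L, lr + 1L)
  for (id in others) slot_w <- pmax(slot_w, nchar(insertions[[id]]))

  build_row <- function(res, ins) {
    pieces <- character(0)
    for (r in 0:lr) {
      piece <- ins[r + 1L]
      piece <- paste0(piece, strrep("-", slot_w[r + 1L] - nchar(piece)))
      if (r > 0L) piece <- paste0(res[r], piece)
      pieces <- c(pieces, piece)
    }
    paste(pieces, collapse = "")
  }
  rows <- c(stats::setNames(build_row(strsplit(ref, "")[[1]], rep("", lr + 1L)), ref_id),
            vapply(others, function(id) build_row(aligned_to_ref[[id]], insertions[[id]]), ""))
  rows <- rows[names(seqs)]
  structure(rows, class = "protein_msa", reference = ref_id)
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("<protein_msa> %d sequences x %d columns (reference: %s)\n",
              length(x), nchar(x[[1]]), attr(x, "reference")))
  invisible(x)
}

#' Per-column conservation profile of an alignment
#'
#' Information content per column is `occupancy * (log2(20) - H)` where `H`
#' is the Shannon entropy of the residue frequencies with a pseudocount of
#' 1/20 per residue, and occupancy is the non-gap fraction. Gap-only columns
#' get IC 0. No background-composition or small-sample correction is applied.
#'
#' @param msa a `protein_msa` (or named character vector of equal-length
#'   aligned rows).
#' @return tibble of class `conservation_profile` with columns: column, ic,
#'   occupancy, consensus, consensus_freq; residue frequency matrix (20 x
#'   ncol, gap-excluded, no pseudocount) in attribute `freqs`.
#' @export
column_information <- function(msa) {
  rows <- unclass(msa)
  stopifnot(length(rows) >= 1L)
  mat <- do.call(rbind, strsplit(rows, ""))
  nc <- ncol(mat)
  freqs <- matrix(0, nrow = length(.aa20), ncol = nc, dimnames = list(.aa20, NULL))
  ic <- numeric(nc); occ <- numeric(nc)
  consensus <- character(nc); consensus_freq <- numeric(nc)
  for (j in seq_len(nc)) {
    col <- mat[, j]
    res <- col[col %in% .aa20]
    occ[j] <- length(res) / length(col)
    if (length(res) == 0L) {
      ic[j] <- 0; consensus[j] <- "-"; consensus_freq[j] <- 0
      next
    }
    counts <- table(factor(res, levels = .aa20))
    freqs[, j] <- as.numeric(counts) / length(res)
    p <- (as.numeric(counts) + 1 / 20) / (length(res) + 1)
    h <- -sum(p * log2(p))
    ic[j] <- occ[j] * (log2(20) - h)
    consensus[j] <- .aa20[which.max(counts)]
    consensus_freq[j] <- max(as.numeric(counts)) / length(res)
  }
  out <- tibble(column = seq_len(nc), ic = ic, occupancy = occ,
                consensus = consensus, consensus_freq = consensus_freq)
  attr(out, "freqs") <- freqs
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Select candidate primer-anchor motif windows from a conservation profile
#'
#' Slides windows of `win_len` columns, ranks them by mean information
#' content (ties toward the smaller column index) and renders each returned
#' window as a motif pattern: positions whose modal-residue frequency falls
#' below `wildcard_threshold` become the wildcard `x`.
#'
#' @param profile a `conservation_profile`.
#' @param win_len window length in columns (4-6 typical).
#' @param top_k number of windows to return (> 0).
#' @param wildcard_threshold modal-residue frequency below which a position
#'   is wildcarded (default 0.5).
#' @param overlap allow overlapping windows (default FALSE: greedy
#'   non-overlapping selection down the ranking).
#' @return tibble: start_col, end_col, mean_ic, pattern.
#' @export
select_motif_windows <- function(profile, win_len = 4L, top_k = 3L,
                                 wildcard_threshold = 0.5, overlap = FALSE) {
  if (top_k <= 0L) stop("top_k must be positive", call. = FALSE)
  nc <- nrow(profile)
  stopifnot(nc >= win_len)
  starts <- seq_len(nc - win_len + 1L)
  mean_ic <- vapply(starts, function(s) mean(profile$ic[s:(s + win_len - 1L)]), 0)
  ord <- order(-mean_ic, starts)
  chosen <- integer(0)
  for (s in starts[ord]) {
    if (length(chosen) >= top_k) break
    if (!overlap && any(abs(chosen - s) < win_len)) next
    chosen <- c(chosen, s)
  }
  pattern_of <- function(s) {
    idx <- s:(s + win_len - 1L)
    chars <- ifelse(profile$consensus_freq[idx] >= wildcard_threshold,
                    profile$consensus[idx], "x")
    paste(chars, collapse = "")
  }
  tibble(start_col = chosen, end_col = chosen + win_len - 1L,
         mean_ic = mean_ic[match(chosen, starts)],
         pattern = vapply(chosen, pattern_of, ""))
}

#' Read the residues of an alignment window for every row
#'
#' Residues are read from the alignment columns of the chosen window (not by
#' re-scanning the unaligned sequences), so per-homologue motif variants line
#' up with the window the profile selected.
#'
#' @param msa a `protein_msa`.
#' @param start_col first alignment column of the window.
#' @param win_len window length.
#' @return named character vector of window strings (may contain `-`).
#' @export
motif_window_variants <- function(msa, start_col, win_len) {
  rows <- unclass(msa)
  vapply(rows, function(r) substr(r, start_col, start_col + win_len - 1L), "")
}

#' Count motif-pattern matches among window variants
#'
#' The wildcard `x` in a pattern matches any residue. A more specific
#' pattern can never count higher than any of its generalizations.
#'
#' @param variants character vector of window strings, all the same length
#'   as the patterns.
#' @param patterns character vector of patterns over amino-acid letters and
#'   `x`.
#' @return tibble: pattern, count.
#' @export
count_motif_patterns <- function(variants, patterns) {
  plen <- unique(nchar(patterns))
  if (length(plen) != 1L || any(nchar(variants) != plen)) {
    stop("variants and patterns must all have the same length", call. = FALSE)
  }
  vmat <- do.call(rbind, strsplit(toupper(variants), ""))
  counts <- vapply(patterns, function(p) {
    pc <- strsplit(p, "")[[1]]
    fixed <- pc != "x"
    if (!any(fixed)) return(length(variants))
    sum(apply(vmat[, fixed, drop = FALSE], 1L,
              function(row) all(row == toupper(pc[fixed]))))
  }, integer(1))
  tibble(pattern = patterns, count = unname(counts))
}

#' Estimate the amplifiable fraction of gene pairs by motif co-occurrence
#'
#' Co-occurrence of the two primer-anchor motifs in a gene pair is used as a
#' proxy for amplification success: a pair is counted amplifiable when its
#' receptor-side and synthase-side window variants both match their
#' respective patterns.
#'
#' @param receptor_variants,synthase_variants index-paired window strings
#'   (same gene-pair order).
#' @param receptor_pattern,synthase_pattern patterns with wildcard `x`.
#' @return one-row tibble: n_pairs, n_amplifiable, percent (one decimal).
#' @export
estimate_amplifiable <- function(receptor_variants, synthase_variants,
                                 receptor_pattern, synthase_pattern) {
  if (length(receptor_variants) != length(synthase_variants)) {
    stop("variant lists must be index-paired (equal length)", call. = FALSE)
  }
  match_pat <- function(vars, pat) {
    pc <- strsplit(pat, "")[[1]]
    fixed <- which(pc != "x")
    vapply(vars, function(v) {
      vc <- strsplit(toupper(v), "")[[1]]
      length(vc) == length(pc) && all(vc[fixed] == toupper(pc[fixed]))
    }, logical(1))
  }
  both <- match_pat(receptor_variants, receptor_pattern) &
    match_pat(synthase_variants, synthase_pattern)
  n <- length(receptor_variants)
  amp <- sum(both)
  tibble(n_pairs = n, n_amplifiable = amp,
         percent = if (n == 0L) 0.0 else round(100 * amp / n, 1))
}

#' Write an alignment as aligned FASTA
#' @param msa a `protein_msa`.
#' @param path output path.
#' @export
write_msa_fasta <- function(msa, path) {
  write_fasta(unclass(msa), path)
}

#' Conservation profile plot
#'
#' Per-column information content with occupancy shading, the
#' sequence-logo-style summary used to eyeball candidate anchor windows.
#'
#' @param object a `conservation_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.conservation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$column, y = .data$ic)) +
    ggplot2::geom_col(ggplot2::aes(alpha = .data$occupancy), fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$consensus), vjust = -0.3, size = 2.5) +
    ggplot2::scale_alpha_continuous(range = c(0.3, 1), limits = c(0, 1)) +
    ggplot2::labs(x = "alignment column", y = "information content (bits)",
                  alpha = "occupancy") +
    ggplot2::theme_minimal()
}
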
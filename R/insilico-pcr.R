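# Degenerate primer matching with 3'-aware mismatch rules, amplicon
# prediction, and priming-likelihood classification of binding-site variants.

# 4-bit base masks; degenerate-vs-degenerate compatibility is set
# intersection. Template N encodes as 0 so it never matches (nonspecific
# annealing is not assumed).
.base_mask <- local({
  m <- vapply(.iupac_sets, function(s) {
    sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[s])
  }, integer(1))
  m["N"] <- 15L
  m
})

.mask_template <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  out <- unname(.base_mask[chars])
  out[is.na(out) | chars == "N"] <- 0L
  out
}

.mask_primer <- function(seq) {
  check_iupac(seq)
  unname(.base_mask[strsplit(toupper(seq), "")[[1]]])
}

# scan one primer orientation over the template; dist3[i] = distance of
# primer index i from the primer's 3' end under this orientation
.scan_masks <- function(pm, tm, max_mismatch, three_prime_exact, dist3) {
  L <- length(pm)
  n_off <- length(tm) - L + 1L
  if (n_off < 1L) return(NULL)
  mm_total <- integer(n_off)
  mm_3p <- integer(n_off)
  for (i in seq_len(L)) {
    incompat <- bitwAnd(pm[i], tm[i:(i + n_off - 1L)]) == 0L
    mm_total <- mm_total + incompat
    if (dist3[i] < three_prime_exact) mm_3p <- mm_3p + incompat
  }
  hit <- which(mm_total <= max_mismatch & mm_3p == 0L)
  if (length(hit) == 0L) return(NULL)
  list(start = hit, mm = mm_total[hit],
       mm_pos = lapply(hit, function(o) {
         idx <- which(bitwAnd(pm, tm[o:(o + L - 1L)]) == 0L)
         sort(dist3[idx])
       }))
}

#' Match a degenerate primer against a template
#'
#' A site matches when at most `max_mismatch` positions fail IUPAC
#' set-intersection compatibility and no failure falls within the
#' 3'-terminal `three_prime_exact` bases (3' mismatches abolish priming).
#' Both template strands are scanned; matches are reported in template (plus
#' strand) coordinates. Strand `+` means the primer sequence matches the
#' plus strand (the primer anneals to the minus strand and extends
#' rightward); strand `-` is the mirror case, extending leftward.
#'
#' @param primer a `degenerate_primer` or IUPAC string.
#' @param template DNA string over A/C/G/T/N.
#' @param max_mismatch maximum tolerated mismatches outside the 3' window
#'   (default 0).
#' @param three_prime_exact length of the 3'-terminal window that must match
#'   exactly (default 3).
#' @param contig_id contig label recorded on the matches.
#' @return tibble: contig_id, start, end (1-based inclusive site interval),
#'   strand, mismatches, mismatch_dist3 (list of distances from the 3' end).
#' @export
match_primer <- function(primer, template, max_mismatch = 0L,
                         three_prime_exact = 3L, contig_id = "template") {
  seq <- if (inherits(primer, "degenerate_primer")) primer$sequence else primer
  L <- nchar(seq)
  tm <- .mask_template(template)
  rows <- list()
  plus <- .scan_masks(.mask_primer(seq), tm, max_mismatch, three_prime_exact,
                      dist3 = (L - 1L):0L)
  if (!is.null(plus)) {
    rows[[1]] <- tibble(contig_id = contig_id, start = plus$start,
                        end = plus$start + L - 1L, strand = "+",
                        mismatches = plus$mm, mismatch_dist3 = plus$mm_pos)
  }
  minus <- .scan_masks(.mask_primer(revcomp(seq)), tm, max_mismatch,
                       three_prime_exact, dist3 = 0L:(L - 1L))
  if (!is.null(minus)) {
    rows[[length(rows) + 1L]] <- tibble(contig_id = contig_id, start = minus$start,
                                        end = minus$start + L - 1L, strand = "-",
                                        mismatches = minus$mm,
                                        mismatch_dist3 = minus$mm_pos)
  }
  if (length(rows) == 0L) {
    return(tibble(contig_id = character(), start = integer(), end = integer(),
                  strand = character(), mismatches = integer(),
                  mismatch_dist3 = list()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$start, .data$strand)
}

#' Predict PCR amplicons from a degenerate primer pair
#'
#' Every inward-facing combination of a plus-strand site of one primer and a
#' downstream minus-strand site of the other yields a product; its length is
#' measured from the 5'-most base of one primer site to the 5'-most base of
#' the other, inclusive of both primer footprints. Products outside
#' `[min_size, max_size]` are dropped.
#'
#' @param fwd,rev_ distinct `degenerate_primer`s (or IUPAC strings).
#' @param template DNA string.
#' @param min_size,max_size product size window in bp (defaults 100 and
#'   3000; true screen bands fall around 500-700 bp, the window is wider on
#'   purpose).
#' @param max_mismatch,three_prime_exact forwarded to [match_primer()].
#' @param contig_id contig label.
#' @return tibble: contig_id, start, end, length, fwd_primer, rev_primer,
#'   fwd_strand, mismatches (summed over both sites).
#' @export
predict_amplicons <- function(fwd, rev_, template, min_size = 100L,
                              max_size = 3000L, max_mismatch = 0L,
                              three_prime_exact = 3L, contig_id = "template") {
  name_of <- function(p, default) {
    if (inherits(p, "degenerate_primer")) p$name else default
  }
  seq_of <- function(p) if (inherits(p, "degenerate_primer")) p$sequence else p
  if (identical(seq_of(fwd), seq_of(rev_))) {
    stop("forward and reverse primers must be distinct", call. = FALSE)
  }
  mf <- match_primer(fwd, template, max_mismatch, three_prime_exact, contig_id)
  mr <- match_primer(rev_, template, max_mismatch, three_prime_exact, contig_id)
  combos <- list(list(left = mf, right = mr, ln = name_of(fwd, "fwd"), rn = name_of(rev_, "rev")),
                 list(left = mr, right = mf, ln = name_of(rev_, "rev"), rn = name_of(fwd, "fwd")))
  out <- purrr::map_dfr(combos, function(cb) {
    lp <- cb$left[cb$left$strand == "+", , drop = FALSE]
    rp <- cb$right[cb$right$strand == "-", , drop = FALSE]
    if (nrow(lp) == 0L || nrow(rp) == 0L) return(NULL)
    grid <- tidyr::expand_grid(li = seq_len(nrow(lp)), ri = seq_len(nrow(rp)))
    purrr::map_dfr(seq_len(nrow(grid)), function(k) {
      a <- lp[grid$li[k], ]; b <- rp[grid$ri[k], ]
      if (b$start <= a$start) return(NULL)
      len <- b$end - a$start + 1L
      if (len < min_size || len > max_size) return(NULL)
      tibble(contig_id = contig_id, start = a$start, end = b$end, length = len,
             fwd_primer = cb$ln, rev_primer = cb$rn,
             mismatches = a$mismatches + b$mismatches)
    })
  })
  if (nrow(out) == 0L) {
    return(tibble(contig_id = character(), start = integer(), end = integer(),
                  length = integer(), fwd_primer = character(),
                  rev_primer = character(), mismatches = integer()))
  }
  dplyr::distinct(dplyr::arrange(out, .data$start, .data$end),
                  .data$contig_id, .data$start, .data$end, .keep_all = TRUE)
}

.prime_levels <- c("will_prime", "will_likely_prime", "might_not_prime", "will_not_prime")

#' Classify the priming likelihood of a binding-site motif variant
#'
#' Works at the nucleotide level: for each motif position the variant
#' residue's codons (all synonymous codons) are compared with the primer's
#' 3'-proximal codon pattern on the coding strand, and the minimum number of
#' incompatible bases is recorded. The wildcard `x` denotes an unobserved
#' residue. Classification, worst outcome wins:
#' * `will_not_prime` - >= 2 incompatible bases within the first two motif
#'   codons (the primer's 3'-terminal six bases), or >= 3 in total;
#' * `might_not_prime` - a single incompatible base in the first two codons,
#'   1-2 incompatible bases in interior codons, or `x` in the first two
#'   codons;
#' * `will_likely_prime` - `x` at an interior or last position, or
#'   incompatibilities confined to the codon of the motif's last residue
#'   (which does not reach the primer's 3' end);
#' * `will_prime` - every position compatible.
#'
#' @param variant motif string over residues and `x`, same length as
#'   `reference`.
#' @param reference the primer's motif pattern (may contain `x`).
#' @param primer the `degenerate_primer` whose 3' end covers the motif.
#' @param codon_table codon usage table (codons per residue).
#' @return ordered factor with levels will_prime > will_likely_prime >
#'   might_not_prime > will_not_prime.
#' @export
classify_priming <- function(variant, reference, primer,
                             codon_table = codon_usage_table()) {
  if (nchar(variant) != nchar(reference)) {
    stop("variant and reference motif must have the same length", call. = FALSE)
  }
  n <- nchar(reference)
  coding <- revcomp(if (inherits(primer, "degenerate_primer")) primer$sequence else primer)
  stopifnot(nchar(coding) >= 3L * n)
  vres <- strsplit(toupper(variant), "")[[1]]
  is_x <- vres == "X"
  d <- rep(NA_real_, n)
  for (i in which(!is_x)) {
    pr_codon <- substr(coding, 3L * i - 2L, 3L * i)
    pm <- .mask_primer(pr_codon)
    cods <- codons_for(vres[i], codon_table)
    d[i] <- min(vapply(cods, function(cd) {
      cm <- .mask_primer(cd)
      sum(bitwAnd(cm, pm) == 0L)
    }, 0))
  }
  first_two <- seq_len(min(2L, n))
  interior <- seq_len(n - 1L)
  will_not <- any(d[first_two] >= 2, na.rm = TRUE) || sum(d, na.rm = TRUE) >= 3
  might_not <- any(is_x[first_two]) ||
    any(d[interior] >= 1, na.rm = TRUE)
  will_likely <- any(is_x[-first_two]) || isTRUE(d[n] >= 1)
  cls <- if (will_not) "will_not_prime" else if (might_not) "might_not_prime" else
    if (will_likely) "will_likely_prime" else "will_prime"
  factor(cls, levels = .prime_levels, ordered = TRUE)
}

#' Write amplicon predictions as TSV
#' @param amplicons amplicon tibble.
#' @param path output path.
#' @export
write_amplicons_tsv <- function(amplicons, path) {
  readr::write_tsv(amplicons, path)
  invisible(path)
}
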
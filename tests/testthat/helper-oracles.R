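# Independent oracles and small simulation helpers shared across the suite.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Quadratic affine-gap Smith-Waterman, independent of the alignment engine
# the package uses. Gap of length L costs open + L * extend (matching the
# engine's penalty convention).
sw_score_oracle <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1) # gap in a (consuming b)
  Fm <- matrix(-Inf, n + 1, m + 1) # gap in b (consuming a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      Fm[i, j] <- max(H[i - 1, j] - open - extend, Fm[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[ac[i - 1], bc[j - 1]], E[i, j], Fm[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Brute-force degenerate primer matcher: expand the primer and slide every
# concrete word over both strands. Returns sorted "start:strand" keys.
match_oracle <- function(primer_seq, template) {
  w <- nchar(primer_seq)
  hits <- character(0)
  tpl <- toupper(template)
  n <- nchar(tpl)
  if (n >= w) {
    words <- substring(tpl, 1:(n - w + 1L), w:n)
    plus_at <- which(words %in% expand_degenerate(primer_seq) & !grepl("N", words))
    minus_at <- which(words %in% expand_degenerate(revcomp(primer_seq)) &
                        !grepl("N", words))
    if (length(plus_at) > 0L) hits <- c(hits, paste0(plus_at, ":+"))
    if (length(minus_at) > 0L) hits <- c(hits, paste0(minus_at, ":-"))
  }
  sort(hits)
}

match_keys <- function(matches) {
  if (nrow(matches) == 0L) return(character(0))
  sort(paste0(matches$start, ":", matches$strand))
}

# mutate each unprotected position with probability `rate`
mutate_protein <- function(prot, rate, protect = integer(0)) {
  ch <- strsplit(prot, "")[[1]]
  for (i in setdiff(seq_along(ch)[-1], protect)) {
    if (stats::runif(1) < rate) ch[i] <- sample(setdiff(AA20, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

# toy CDS feature tibble builder for pairing tests (no alignment involved)
toy_hits <- function(contig, starts, ends, strands, prefix = "g") {
  tibble::tibble(contig_id = contig, start = as.integer(starts),
                 end = as.integer(ends), strand = strands,
                 locus_tag = paste0(prefix, seq_along(starts)),
                 protein = "M", query_id = prefix, score = 100,
                 bits = 50, evalue = 1e-30, identity = 1)
}

random_dna <- function(n, gc = 0.7) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  table(paste0(ch[-length(ch)], ch[-1]))
}

# alignment column index of every reference residue
.query_cols_of <- function(msa) {
  ref <- attr(msa, "reference")
  which(strsplit(unclass(msa)[[ref]], "")[[1]] != "-")
}

scb_test_primers <- function() {
  tab <- codon_usage_table()
  pol <- scb_policies()
  list(
    fwd = design_primer(pol$scb_F$context, pol$scb_F$policy, tab,
                        role = "receptor", name = "scb_F", motif_len = 4L),
    rev = design_primer(pol$scb_R$context, pol$scb_R$policy, tab,
                        role = "synthase", name = "scb_R", motif_len = 5L),
    table = tab)
}
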
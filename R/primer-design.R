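# Codon-usage-aware back-translation of protein anchor contexts into IUPAC
# degenerate primers. Primers are written antisense to the coding strand so
# that the conserved motif (the context's N-terminal residues) sits at the
# primer's 3' end.

#' Parse an anchor context string
#'
#' Contexts are amino-acid strings in which a position may carry an explicit
#' residue set in braces, e.g. `"ET{ILV}RQSG"`.
#'
#' @param context context string.
#' @return list of character vectors, one allowed-residue set per position.
#' @export
parse_context <- function(context) {
  out <- list()
  chars <- strsplit(toupper(context), "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "{") {
      j <- i + 1L
      set <- character(0)
      while (j <= length(chars) && chars[j] != "}") {
        set <- c(set, chars[j]); j <- j + 1L
      }
      if (j > length(chars)) stop("unclosed '{' in context", call. = FALSE)
      if (length(set) == 0L) stop("empty residue set in context", call. = FALSE)
      out[[length(out) + 1L]] <- set
      i <- j + 1L
    } else {
      if (!chars[i] %in% .aa20) {
        stop(sprintf("invalid residue '%s' in context", chars[i]), call. = FALSE)
      }
      out[[length(out) + 1L]] <- chars[i]
      i <- i + 1L
    }
  }
  out
}

.context_string <- function(sets) {
  paste(vapply(sets, function(s) {
    if (length(s) == 1L) s else paste0("{", paste(s, collapse = ""), "}")
  }, ""), collapse = "")
}

#' Build a per-position degeneracy policy
#'
#' A policy assigns one codon-choice rule to every context position:
#' * `full` - all synonymous codons, collapsed to the minimal IUPAC codon;
#' * `top2` - the two most frequent codons by the usage table, collapsed;
#' * `top1` - the single most frequent codon;
#' * `codon` - an explicitly pinned codon (via `codons`);
#' * `residue_set` - union of the top-2 codons of each residue in the
#'   position's allowed set, collapsed to the minimal IUPAC cover.
#'
#' @param rules character vector of rules, one per context position.
#' @param codons optional character vector of explicit codons (NA where the
#'   rule is not `codon`).
#' @return tibble of class `degeneracy_policy`.
#' @export
degeneracy_policy <- function(rules, codons = NULL) {
  allowed <- c("full", "top2", "top1", "codon", "residue_set")
  stopifnot(all(rules %in% allowed))
  if (is.null(codons)) codons <- rep(NA_character_, length(rules))
  stopifnot(length(codons) == length(rules))
  if (any(rules == "codon" & is.na(codons))) {
    stop("rule 'codon' requires an explicit codon", call. = FALSE)
  }
  out <- tibble(position = seq_along(rules), rule = rules, codon = toupper(codons))
  class(out) <- c("degeneracy_policy", class(out))
  out
}

#' Bundled degeneracy policies of the scb screening primers
#'
#' The per-position rules reproduce the published scb_F/scb_R degenerate
#' primers exactly from their anchor contexts with the bundled codon usage
#' table: scb_F uses fully degenerate codons across the YFHF motif, a top-2
#' wobble at P and single codons toward the 5' end (the Arg position is
#' pinned to CGG, the second-ranked Arg codon); scb_R uses full degeneracy at
#' E, top-2 at T, the {I,L,V} residue-set codon VTB, and single codons for
#' RQSG. These rules are the package's ground truth for the primers, not a
#' claim about how they were originally derived.
#'
#' @return named list with elements `scb_F` and `scb_R`, each a list of
#'   `context`, `policy` and `role`.
#' @export
scb_policies <- function() {
  list(
    scb_F = list(
      context = "YFHFPSKER",
      role = "receptor",
      motif_len = 4L,
      policy = degeneracy_policy(
        rules = c("full", "full", "full", "full", "top2", "top1", "top1", "top1", "codon"),
        codons = c(NA, NA, NA, NA, NA, NA, NA, NA, "CGG"))),
    scb_R = list(
      context = "ET{ILV}RQSG",
      role = "synthase",
      motif_len = 5L,
      policy = degeneracy_policy(
        rules = c("full", "top2", "residue_set", "top1", "top1", "top1", "top1"))))
}

#' Back-translate an anchor context into coding-sense IUPAC DNA
#'
#' @param context context string, possibly with `{...}` residue sets
#'   (length 1-10 positions), or a parsed context list.
#' @param policy a [degeneracy_policy()] with one rule per position.
#' @param table codon usage table (default the bundled Streptomyces table).
#' @return IUPAC DNA string of length `3 * positions`, coding sense.
#' @export
back_translate <- function(context, policy, table = codon_usage_table()) {
  sets <- if (is.list(context)) context else parse_context(context)
  if (length(sets) < 1L || length(sets) > 10L) {
    stop("context must have 1-10 positions", call. = FALSE)
  }
  if (nrow(policy) != length(sets)) {
    stop("policy must assign exactly one rule per context position", call. = FALSE)
  }
  codons <- vapply(seq_along(sets), function(i) {
    res <- sets[[i]]
    rule <- policy$rule[i]
    if (rule == "residue_set") {
      if (length(res) == 0L) stop("empty residue set", call. = FALSE)
      cods <- unlist(lapply(res, codons_for, table = table, top = 2L))
      return(iupac_merge(cods))
    }
    if (length(res) != 1L) {
      stop(sprintf("rule '%s' at position %d requires a single residue", rule, i),
           call. = FALSE)
    }
    switch(rule,
      full = iupac_merge(codons_for(res, table)),
      top2 = iupac_merge(codons_for(res, table, top = 2L)),
      top1 = codons_for(res, table, top = 1L),
      codon = policy$codon[i])
  }, character(1))
  paste(codons, collapse = "")
}

#' Design a degenerate primer from an anchor context
#'
#' The context's N-terminal residues are the conserved motif; the primer is
#' the reverse complement of the back-translated context, so its 3'-terminal
#' base pairs with the first base of the motif's first codon and mismatches
#' in the motif fall in the primer's 3' region, where they matter most.
#'
#' @param context anchor context (motif first), e.g. `"YFHFPSKER"`.
#' @param policy a [degeneracy_policy()].
#' @param table codon usage table.
#' @param role target gene role, `"receptor"` or `"synthase"`.
#' @param name primer name.
#' @param motif_len number of N-terminal context positions forming the motif.
#' @param max_degeneracy refuse designs above this pool size (default 512).
#' @return object of class `degenerate_primer`.
#' @export
design_primer <- function(context, policy, table = codon_usage_table(),
                          role = c("receptor", "synthase"), name = "primer",
                          motif_len = 4L, max_degeneracy = 512L) {
  role <- match.arg(role)
  coding <- back_translate(context, policy, table)
  seq <- revcomp(coding)
  d <- degeneracy(seq)
  if (d > max_degeneracy) {
    stop(sprintf("degeneracy %d exceeds cap %d; tighten the policy", d, max_degeneracy),
         call. = FALSE)
  }
  sets <- if (is.list(context)) context else parse_context(context)
  structure(list(name = name, sequence = seq, role = role,
                 context = sets, context_string = .context_string(sets),
                 motif_len = as.integer(motif_len), coding = coding,
                 policy = policy, degeneracy = d),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s): 5'-%s-3' (degeneracy %d, context %s)\n",
              x$name, x$role, x$sequence, x$degeneracy, x$context_string))
  invisible(x)
}

#' Per-expansion GC content and Wallace-rule melting temperature
#'
#' @param primer a `degenerate_primer` or IUPAC string.
#' @return tibble: expansion, gc (fraction), tm_wallace (deg C, 2(A+T)+4(G+C)).
#' @export
primer_expansions <- function(primer) {
  seq <- if (inherits(primer, "degenerate_primer")) primer$sequence else primer
  ex <- expand_degenerate(seq)
  gc <- vapply(ex, function(s) {
    b <- strsplit(s, "")[[1]]; mean(b %in% c("G", "C"))
  }, 0)
  at <- nchar(seq) * (1 - gc)
  tibble(expansion = ex, gc = unname(gc),
         tm_wallace = unname(2 * at + 4 * nchar(seq) * gc))
}

#' Verify a degenerate primer by translating its reverse complement
#'
#' Expands the primer's coding-sense reverse complement codon by codon and
#' reports the residue set each codon can encode. The round-trip property
#' `verify(design(context))` always covers the context's allowed sets; some
#' positions over-cover (e.g. the {I,L,V} codon VTB also admits M via ATG).
#'
#' @param primer a `degenerate_primer` or IUPAC string with length divisible
#'   by 3.
#' @return tibble: position, codon (IUPAC), residues (collapsed string),
#'   has_stop.
#' @export
verify_primer <- function(primer) {
  seq <- if (inherits(primer, "degenerate_primer")) primer$sequence else primer
  if (nchar(seq) %% 3L != 0L) stop("primer length must be divisible by 3", call. = FALSE)
  coding <- revcomp(seq)
  n <- nchar(coding) / 3L
  purrr::map_dfr(seq_len(n), function(i) {
    codon <- substr(coding, 3L * i - 2L, 3L * i)
    aas <- sort(unique(vapply(expand_degenerate(codon), translate_dna, "")))
    tibble(position = i, codon = codon,
           residues = paste(setdiff(aas, "*"), collapse = ""),
           has_stop = "*" %in% aas)
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a degenerate primer into a one-row tibble
#'
#' @param x a `degenerate_primer`.
#' @param ... unused.
#' @return tibble: name, role, sequence, length, degeneracy, context,
#'   gc_min/gc_max, tm_min/tm_max.
#' @exportS3Method generics::tidy
tidy.degenerate_primer <- function(x, ...) {
  ex <- primer_expansions(x)
  tibble(name = x$name, role = x$role, sequence = x$sequence,
         length = nchar(x$sequence), degeneracy = x$degeneracy,
         context = x$context_string,
         gc_min = min(ex$gc), gc_max = max(ex$gc),
         tm_min = min(ex$tm_wallace), tm_max = max(ex$tm_wallace))
}

#' Write primers as TSV
#' @param primers list of `degenerate_primer` objects.
#' @param path output path.
#' @export
write_primers_tsv <- function(primers, path) {
  readr::write_tsv(dplyr::bind_rows(lapply(primers, tidy)), path)
  invisible(path)
}
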
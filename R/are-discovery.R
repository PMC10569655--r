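# EM-based ungapped DNA motif discovery (ZOOPS/OOPS) for recovering the
# palindromic autoregulatory response element shared by intergenic/amplicon
# sequences. The numeric core (E/M steps, seed screening) lives in src/.

.dna4 <- c("A", "C", "G", "T")

.encode_dna <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], .dna4) - 1L
  if (anyNA(x)) stop("motif discovery requires sequences over A/C/G/T", call. = FALSE)
  x
}

.rc_encoded <- function(x) rev(3L - x)

.decode_dna <- function(x) paste(.dna4[x + 1L], collapse = "")

# run expr with a local, restored RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: returns a random sequence with exactly the same
#' dinucleotide counts (and first/last base) as the input, the standard null
#' for DNA motif significance.
#'
#' @param seq DNA string.
#' @return shuffled DNA string.
#' @export
dinuc_shuffle <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  if (n <= 3L) return(seq)
  last <- ch[n]
  edges <- split(ch[-1L], factor(ch[-n], levels = unique(ch[-n])))
  verts <- names(edges)
  repeat {
    last_edge <- vapply(edges, function(e) e[sample.int(length(e), 1L)], "")
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      cur <- v; seen <- character(0)
      while (cur != last && !(cur %in% seen)) {
        seen <- c(seen, cur)
        if (!(cur %in% verts)) break
        cur <- last_edge[[cur]]
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  ordered <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v == last) return(e[sample.int(length(e))])
    i <- which(e == last_edge[[v]])[1]
    rest <- e[-i]
    c(rest[sample.int(length(rest))], e[i])
  })
  names(ordered) <- verts
  used <- stats::setNames(rep(0L, length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]
  cur <- ch[1]
  for (k in 2:n) {
    used[cur] <- used[cur] + 1L
    nxt <- ordered[[cur]][used[cur]]
    out[k] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

.background_freq <- function(enc) {
  counts <- tabulate(unlist(enc) + 1L, nbins = 4L)
  p <- (counts + 1) / (sum(counts) + 4)
  # strand-symmetric background: site models compete on both strands
  p <- (p + rev(p)) / 2
  p / sum(p)
}

.enumerate_seeds <- function(enc, w) {
  seeds <- list()
  seen <- new.env(hash = TRUE)
  for (i in seq_along(enc)) {
    x <- enc[[i]]
    for (o in seq_len(length(x) - w + 1L)) {
      key <- paste(x[o:(o + w - 1L)], collapse = "")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        seeds[[length(seeds) + 1L]] <- x[o:(o + w - 1L)]
      }
    }
  }
  do.call(rbind, seeds)
}

# best LLR at width w: screen every distinct w-mer seed with a one-pass
# score, then run EM to convergence from the best seed (ties already resolved
# toward the smaller (sequence, offset) by enumeration order)
.fit_width <- function(enc, rc, w, gamma, bg, match_p, max_iter, tol, beta) {
  seeds <- .enumerate_seeds(enc, w)
  scr <- .screen_seeds_cpp(enc, rc, seeds, gamma, bg, match_p)
  best <- which.max(scr)
  theta0 <- matrix((1 - match_p) / 3, nrow = w, ncol = 4)
  theta0[cbind(seq_len(w), seeds[best, ] + 1L)] <- match_p
  fit <- .zoops_em_cpp(enc, rc, theta0, gamma, bg, as.integer(max_iter), tol, beta)
  fit
}

.extract_sites <- function(fit, enc, ids, w, min_posterior = 0.5) {
  rows <- purrr::map_dfr(seq_along(enc), function(i) {
    zf <- fit$zf[[i]]; zr <- fit$zr[[i]]
    tot <- sum(zf) + sum(zr)
    if (tot < min_posterior) return(NULL)
    if (max(zf) >= max(zr)) {
      o <- which.max(zf)
      tibble(seq_id = ids[i], offset = o, strand = "+", posterior = tot)
    } else {
      o <- which.max(zr)
      L <- length(enc[[i]])
      tibble(seq_id = ids[i], offset = L - w + 2L - o, strand = "-", posterior = tot)
    }
  })
  if (nrow(rows) == 0L) {
    rows <- tibble(seq_id = character(), offset = integer(),
                   strand = character(), posterior = double())
  }
  rows
}

#' Discover a shared ungapped DNA motif by EM
#'
#' Fits a ZOOPS (zero-or-one occurrence per sequence) position weight matrix
#' of each width in `wmin:wmax` by expectation-maximization, searching both
#' strands. Every distinct w-mer of the input seeds the search via a
#' one-pass likelihood screen; the best seed per width is run to convergence
#' (LLR increase below `tol` or `max_iter` iterations). When several widths
#' are scanned, the returned width is the one whose log-likelihood ratio is
#' least attainable on dinucleotide-shuffled data (empirical calibration with
#' `width_shuffles` shuffles per width; ties broken by the larger null
#' z-score, then the smaller width). Deterministic given `seed`.
#'
#' @param seqs character vector of DNA sequences (>= 3, each at least `wmax`
#'   long).
#' @param wmin,wmax motif width range (defaults 15 and 30).
#' @param mode `"zoops"` (site prior `gamma`) or `"oops"` (one site per
#'   sequence).
#' @param seed integer seed for the shuffle calibration.
#' @param gamma ZOOPS site prior (default 0.8).
#' @param width_shuffles shuffles per width for width calibration (default 10).
#' @param max_iter,tol EM stopping rule (default 200 iterations, LLR delta
#'   1e-6).
#' @param beta PWM pseudocount mass (Dirichlet scale towards background).
#' @param match_p seed PWM match probability.
#' @return object of class `motif_model`: pwm (width x 4, rows sum to 1),
#'   width, sites tibble (seq_id, offset 1-based on the input strand, strand,
#'   posterior), llr, llr_trace, palindromicity, significance (NA until
#'   [motif_significance()] is run), background, gamma, seed.
#' @export
discover_motif <- function(seqs, wmin = 15L, wmax = 30L,
                           mode = c("zoops", "oops"), seed = 1L,
                           gamma = 0.8, width_shuffles = 10L,
                           max_iter = 200L, tol = 1e-6, beta = 0.1,
                           match_p = 0.6) {
  mode <- match.arg(mode)
  if (length(seqs) < 3L) stop("motif discovery needs at least 3 sequences", call. = FALSE)
  stopifnot(wmin >= 2L, wmax >= wmin)
  short <- which(nchar(seqs) < wmax)
  if (length(short) > 0L) {
    stop(sprintf("sequence(s) shorter than the maximum width %d: %s",
                 wmax, paste(short, collapse = ",")), call. = FALSE)
  }
  if (mode == "oops") gamma <- 1.0
  ids <- if (!is.null(names(seqs))) names(seqs) else paste0("seq", seq_along(seqs))
  enc <- lapply(seqs, .encode_dna)
  rc <- lapply(enc, .rc_encoded)
  bg <- .background_freq(enc)

  widths <- seq.int(wmin, wmax)
  fits <- lapply(widths, function(w)
    .fit_width(enc, rc, w, gamma, bg, match_p, max_iter, tol, beta))
  obs_llr <- vapply(fits, function(f) f$llr, 0)

  if (length(widths) > 1L) {
    null_llr <- .with_seed(seed, {
      vapply(seq_len(width_shuffles), function(s) {
        sh <- lapply(seqs, dinuc_shuffle)
        enc_s <- lapply(sh, .encode_dna)
        rc_s <- lapply(enc_s, .rc_encoded)
        vapply(widths, function(w) {
          .fit_width(enc_s, rc_s, w, gamma, bg, match_p,
                     max_iter = 20L, tol = tol, beta = beta)$llr
        }, 0)
      }, numeric(length(widths)))
    })
    null_llr <- matrix(null_llr, nrow = length(widths))
    pvals <- vapply(seq_along(widths), function(k)
      (1 + sum(null_llr[k, ] >= obs_llr[k])) / (1 + width_shuffles), 0)
    zs <- vapply(seq_along(widths), function(k) {
      s <- stats::sd(null_llr[k, ])
      if (!is.finite(s) || s == 0) s <- 1
      (obs_llr[k] - mean(null_llr[k, ])) / s
    }, 0)
    best_k <- order(pvals, -zs, widths)[1]
  } else {
    best_k <- 1L
  }
  w <- widths[best_k]
  fit <- fits[[best_k]]
  pwm <- fit$theta
  colnames(pwm) <- .dna4
  model <- structure(list(
    pwm = pwm, width = w,
    sites = .extract_sites(fit, enc, ids, w),
    llr = fit$llr, llr_trace = fit$llr_trace,
    palindromicity = NA_real_, significance = NA_real_,
    background = stats::setNames(bg, .dna4), gamma = gamma, mode = mode,
    seed = seed), class = "motif_model")
  model$palindromicity <- palindromicity(model)
  model
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> width %d, %d sites, LLR %.2f, palindromicity %.3f",
              x$width, nrow(x$sites), x$llr, x$palindromicity))
  if (!is.na(x$significance)) cat(sprintf(", significance %.3g", x$significance))
  cat("\nconsensus:", motif_consensus(x), "\n")
  invisible(x)
}

#' Consensus string of a motif model
#' @param model a `motif_model`.
#' @return character consensus (modal base per column).
#' @export
motif_consensus <- function(model) {
  paste(.dna4[apply(model$pwm, 1L, which.max)], collapse = "")
}

#' Palindromicity of a motif model
#'
#' One minus the mean per-column total-variation distance between the PWM
#' and the reverse complement of its column-reversed self. A perfect
#' inverted repeat scores 1; a poly-A PWM scores 0.
#'
#' @param model a `motif_model` or a width x 4 PWM matrix (columns A,C,G,T).
#' @return score in \[0, 1\].
#' @export
palindromicity <- function(model) {
  pwm <- if (inherits(model, "motif_model")) model$pwm else model
  stopifnot(ncol(pwm) == 4L)
  rc <- pwm[rev(seq_len(nrow(pwm))), c(4L, 3L, 2L, 1L), drop = FALSE]
  tv <- rowSums(abs(pwm - rc)) / 2
  1 - mean(tv)
}

#' Empirical motif significance from a dinucleotide-shuffle null
#'
#' Each of `n_shuffles` shuffled datasets is searched at the model's width
#' (seed screen plus a short EM refinement) and the significance is
#' `(1 + #(null LLR >= observed LLR)) / (1 + n_shuffles)`. This empirical
#' null replaces an analytic E-value; its resolution floor is
#' `1/(1 + n_shuffles)`.
#'
#' @param model a fitted `motif_model`.
#' @param seqs the sequences the model was fitted on.
#' @param n_shuffles number of shuffled datasets (default 200; < 20 warns).
#' @param seed integer seed.
#' @param null_em_iter EM iteration cap for each null fit; defaults to the
#'   same cap as the observed fit so the null and observed statistics get
#'   identical optimization effort.
#' @return the significance value (also stored in the returned model when
#'   assigned back).
#' @export
motif_significance <- function(model, seqs, n_shuffles = 200L, seed = 1L,
                               null_em_iter = 200L) {
  if (n_shuffles < 1L) stop("n_shuffles must be at least 1", call. = FALSE)
  if (n_shuffles < 20L) {
    warning("fewer than 20 shuffles: significance resolution is coarse")
  }
  w <- model$width
  bg <- as.numeric(model$background)
  null_llr <- .with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      sh <- lapply(seqs, dinuc_shuffle)
      enc_s <- lapply(sh, .encode_dna)
      rc_s <- lapply(enc_s, .rc_encoded)
      .fit_width(enc_s, rc_s, w, model$gamma, bg, 0.6,
                 max_iter = null_em_iter, tol = 1e-6, beta = 0.1)$llr
    }, 0)
  })
  (1 + sum(null_llr >= model$llr)) / (1 + n_shuffles)
}

#' @rdname tidy.degenerate_primer
#' @exportS3Method generics::tidy
tidy.motif_model <- function(x, ...) {
  pwm <- x$pwm
  tidyr::pivot_longer(
    dplyr::mutate(as_tibble(pwm), position = seq_len(nrow(pwm))),
    cols = dplyr::all_of(.dna4), names_to = "base", values_to = "prob")
}

#' @rdname tidy.degenerate_primer
#' @exportS3Method generics::glance
glance.motif_model <- function(x, ...) {
  tibble(width = x$width, llr = x$llr, n_sites = nrow(x$sites),
         palindromicity = x$palindromicity, significance = x$significance,
         consensus = motif_consensus(x))
}

#' Sequence-logo-style plot of a motif model
#'
#' Letter heights are the per-column information content apportioned by base
#' probability, the conventional logo scaling.
#'
#' @param object a `motif_model`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.motif_model <- function(object, ...) {
  td <- tidy(object)
  ic <- apply(object$pwm, 1L, function(p) {
    p2 <- p[p > 0]
    2 + sum(p2 * log2(p2))
  })
  td$height <- td$prob * ic[td$position]
  td <- td[order(td$position, td$height), ]
  td <- dplyr::mutate(dplyr::group_by(td, .data$position),
                      ymax = cumsum(.data$height),
                      ymin = .data$ymax - .data$height)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$position - 0.45,
                                    xmax = .data$position + 0.45,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$base), colour = "grey30",
                       linewidth = 0.1) +
    ggplot2::geom_text(ggplot2::aes(y = (.data$ymin + .data$ymax) / 2,
                                    label = .data$base),
                       data = function(d) d[d$height > 0.15, ], size = 2.6) +
    ggplot2::labs(x = "motif position", y = "information content (bits)") +
    ggplot2::theme_minimal()
}

#' Write a motif model in MEME minimal motif format
#'
#' @param model a `motif_model`.
#' @param path output path.
#' @param name motif name.
#' @export
write_motif_meme <- function(model, path, name = "ARE") {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- model$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %s",
                       model$width, nrow(model$sites),
                       ifelse(is.na(model$significance), "NA",
                              format(model$significance, digits = 4)))), con)
  utils::write.table(format(model$pwm, digits = 6), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
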
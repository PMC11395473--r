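#' Background base-composition models
#'
#' A background model is an order-0 (i.i.d.) distribution over A,C,G,T used
#' both to form log-odds weights and as the null for exact p-values.
#' `background_model()` validates an explicit distribution;
#' `promoter_background()` estimates it from the scanned promoter set itself
#' (plant promoters are AT-rich, so a composition-aware null noticeably
#' reduces false positives), with a per-base floor that keeps log-odds finite.
#'
#' @param probs Named numeric vector over A,C,G,T (any order); must be
#'   strictly positive and sum to 1.
#' @return A named probability vector over A,C,G,T.
#' @export
background_model <- function(probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!setequal(names(probs), DNA_BASES)) abort("background needs names A,C,G,T")
  probs <- probs[DNA_BASES]
  if (any(probs <= 0)) abort("background probabilities must be strictly positive")
  if (abs(sum(probs) - 1) > 1e-12) abort("background probabilities must sum to 1")
  probs
}

#' @rdname background_model
#' @param promoters Promoter tibble (needs a `seq` column).
#' @param floor Minimum probability per base (default 0.01).
#' @export
promoter_background <- function(promoters, floor = 0.01) {
  tab <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(promoters$seq))
  counts <- colSums(tab)[DNA_BASES]
  if (sum(counts) == 0) abort("no A/C/G/T bases in promoter set")
  p <- pmax(counts / sum(counts), floor)
  background_model(p / sum(p))
}

#' Build a log-odds position weight matrix from a frequency matrix
#'
#' Column counts are converted to probabilities with a total pseudocount
#' distributed proportionally to the background, then to log2-odds against
#' the background: `w(i,b) = log2(((n(i,b) + pc*bg(b)) / (N(i) + pc)) / bg(b))`.
#' Every column therefore satisfies `sum_b bg(b) * 2^w(i,b) = 1`.
#'
#' @param counts 4 x L numeric matrix (rownames A,C,G,T) of base counts, or a
#'   one-row slice of the tibble returned by [read_jaspar_pfm()].
#' @param background Background model (default uniform).
#' @param pseudocount Total pseudocount per column (default 1), shared among
#'   bases proportionally to the background.
#' @param matrix_id,tf_name Identifiers carried into hit tables.
#' @return An object of class `pwm`: a list with the weight matrix (bits),
#'   the background, pseudocount and identifiers.
#' @export
build_pwm <- function(counts, background = background_model(), pseudocount = 1,
                      matrix_id = "PWM", tf_name = matrix_id) {
  if (is.data.frame(counts)) {
    stopifnot(nrow(counts) == 1L)
    matrix_id <- counts$matrix_id
    tf_name <- counts$tf_name
    counts <- counts$counts[[1L]]
  }
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  colsum <- colSums(counts)
  if (pseudocount == 0 && any(counts == 0)) {
    abort("zero counts with pseudocount 0 give infinite log-odds; use pseudocount > 0")
  }
  probs <- sweep(counts + outer(background, rep(pseudocount, ncol(counts))),
                 2L, colsum + pseudocount, "/")
  weights <- log2(probs / background)
  structure(
    list(
      matrix_id = matrix_id, tf_name = tf_name,
      weights = weights, background = background, pseudocount = pseudocount
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$matrix_id, " (", x$tf_name, "), L = ", ncol(x$weights),
      ", IC = ", round(pwm_information(x), 2), " bits\n", sep = "")
  invisible(x)
}

#' Information content of a PWM (bits)
#'
#' Sum over columns of the Kullback-Leibler divergence of the (pseudocounted)
#' column distribution from the background.
#'
#' @param pwm A `pwm` object.
#' @return Total information content in bits.
#' @export
pwm_information <- function(pwm) {
  probs <- pwm$background * 2^pwm$weights
  sum(probs * pwm$weights)
}

#' Score a site with a PWM
#'
#' Additive log2-odds score of an L-mer. Sites containing `N` have no defined
#' score and return `NA` (the scanner skips such offsets).
#'
#' @param pwm A `pwm` object.
#' @param site Character vector of DNA strings, each of the motif length.
#' @return Numeric scores in bits (`NA` where the site contains `N`).
#' @export
score_site <- function(pwm, site) {
  L <- ncol(pwm$weights)
  if (any(nchar(site) != L)) abort(paste0("site length must be ", L))
  codes <- lapply(strsplit(toupper(site), ""), match, DNA_BASES)
  vapply(codes, function(cd) {
    if (anyNA(cd)) return(NA_real_)
    sum(pwm$weights[cbind(cd, seq_len(L))])
  }, numeric(1))
}

#' Exact score distribution of a PWM under the background
#'
#' Computes the full distribution of the motif score over random i.i.d.
#' background sequence by dynamic programming: weights are discretized to
#' integer units (round-half-even at `scale` units per bit) and the score
#' mass is convolved position by position. The tail function
#' `P(score >= s)` from the suffix-summed mass is the exact p-value used by
#' the scanner, so a stringency such as p < 1e-4 is an exact statement about
#' the discretized score, not an approximation.
#'
#' @param pwm A `pwm` object.
#' @param scale Integer discretization units per bit (default 1000; >= 100).
#' @return An object of class `pwm_dist` with elements `scale`, `iweights`
#'   (integer weight matrix), `min_score` (units), `mass`, `tail` (both
#'   indexed from `min_score`).
#' @export
score_distribution <- function(pwm, scale = 1000L) {
  scale <- as.integer(scale)
  if (scale < 100L) abort("scale must be >= 100 units per bit")
  iw <- matrix(as.integer(round(pwm$weights * scale)), nrow = 4L,
               dimnames = dimnames(pwm$weights))
  L <- ncol(iw)
  lo <- sum(apply(iw, 2L, min))
  hi <- sum(apply(iw, 2L, max))
  width <- hi - lo + 1L
  bg <- pwm$background
  # mass[k] = P(total discretized score = lo + k - 1) after the columns seen so far
  mass <- numeric(width)
  cum_lo <- 0L
  mass[[1L]] <- 1
  cur_width <- 1L
  for (i in seq_len(L)) {
    wcol <- iw[, i]
    new_lo <- cum_lo + min(wcol)
    new_width <- cur_width + max(wcol) - min(wcol)
    new_mass <- numeric(new_width)
    for (b in 1:4) {
      off <- cum_lo + wcol[[b]] - new_lo
      idx <- seq_len(cur_width) + off
      new_mass[idx] <- new_mass[idx] + bg[[b]] * mass[seq_len(cur_width)]
    }
    mass <- new_mass
    cum_lo <- new_lo
    cur_width <- new_width
  }
  tail <- rev(cumsum(rev(mass)))
  structure(
    list(scale = scale, iweights = iw, min_score = lo, mass = mass, tail = tail),
    class = "pwm_dist"
  )
}

#' Tail probability (exact p-value) of a discretized score
#'
#' @param dist A `pwm_dist` object from [score_distribution()].
#' @param score_units Integer score(s) in discretization units.
#' @return `P(score >= score_units)` under the background model.
#' @export
pwm_tail <- function(dist, score_units) {
  idx <- score_units - dist$min_score + 1L
  p <- rep(1, length(idx))
  p[idx > length(dist$tail)] <- 0
  inside <- idx >= 1L & idx <= length(dist$tail)
  p[inside] <- dist$tail[idx[inside]]
  p
}
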
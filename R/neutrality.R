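## Demography-aware null distributions of Tajima's D and empirical tests.

#' Null distribution of Tajima's D under a fitted demography
#'
#' Simulates `reps` independent coalescent replicates under the given
#' demography (and, optionally, interlocus gene conversion for ORF nulls)
#' and records Tajima's D of the focal locus in each. Replicates where D is
#' undefined (no segregating sites) are kept as NA and excluded from
#' quantiles, with their count reported.
#'
#' @param params a [sim_params()] object describing the null model (sample
#'   sizes, theta, demography, and `C` for conversion-aware nulls; use
#'   `n_B = 0, C = 0` for a plain single-locus null).
#' @param locus which locus the statistic is computed at ("A" or "B").
#' @param reps number of replicates (>= 100).
#' @param seed optional integer seed.
#' @return object of class `null_distribution`: list with `samples`,
#'   `n_undefined`, `statistic`, `params`, `seed`.
#' @export
null_distribution <- function(params, locus = "A", reps = 2000, seed = NULL) {
  stopifnot(inherits(params, "sim_params"), reps >= 100)
  if (!is.null(seed)) set.seed(seed)
  mat_name <- if (locus == "A") "mat_A" else "mat_B"
  samples <- vapply(seq_len(reps), function(i) {
    r <- sim_once(params)
    m <- r[[mat_name]]
    cnt <- colSums(m)
    n <- nrow(m)
    S <- sum(cnt > 0 & cnt < n)
    pi_total <- sum(cnt * (n - cnt)) / (n * (n - 1) / 2)
    tajima_d_core(n, S, pi_total)
  }, 0)
  structure(list(samples = samples, n_undefined = sum(is.na(samples)),
                 statistic = "tajimas_d", locus = locus,
                 params = params, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null distribution of %s (locus %s): %d replicates, %d undefined\n",
              x$statistic, x$locus, length(x$samples), x$n_undefined))
  invisible(x)
}

null_samples <- function(null) {
  s <- if (inherits(null, "null_distribution")) null$samples else null
  s[!is.na(s)]
}

#' Empirical p-value against a simulated null
#'
#' Add-one (pseudo-count) empirical p-values, which never return exactly 0
#' from a finite simulation: upper tail p = (1 + #{null >= observed}) /
#' (reps + 1). The default is the upper tail (balancing selection predicts
#' high Tajima's D); lower and two-tailed variants are analogous, the
#' two-tailed value being twice the smaller tail capped at 1.
#'
#' @param observed observed statistic value.
#' @param null a `null_distribution` or numeric vector of null samples.
#' @param tail "upper", "lower" or "two-sided".
#' @return p-value in (0, 1].
#' @export
empirical_p <- function(observed, null, tail = c("upper", "lower",
                                                 "two-sided")) {
  tail <- match.arg(tail)
  s <- null_samples(null)
  if (length(s) == 0) stop("empty null distribution")
  r <- length(s)
  up <- (1 + sum(s >= observed)) / (r + 1)
  lo <- (1 + sum(s <= observed)) / (r + 1)
  switch(tail,
         upper = up,
         lower = lo,
         `two-sided` = min(1, 2 * min(up, lo)))
}

#' Empirical confidence-interval bounds of a null distribution
#'
#' Symmetric empirical quantiles ((1-level)/2, 1-(1-level)/2) of the null
#' samples.
#'
#' @param null a `null_distribution` or numeric vector.
#' @param level confidence level in (0, 1).
#' @return numeric `c(lo, hi)`.
#' @export
ci_bounds <- function(null, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  s <- null_samples(null)
  if (length(s) == 0) stop("empty null distribution")
  stats::quantile(s, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
}

#' Test an observed Tajima's D against its demographic null
#'
#' Reports both one-sided and the two-sided p-values together with the 95%
#' and 99% empirical intervals, so the tail convention is explicit in the
#' output.
#'
#' @param observed observed Tajima's D.
#' @param null a `null_distribution`.
#' @return list with `p_upper`, `p_lower`, `p_two_sided`, `ci95`, `ci99`,
#'   `observed`.
#' @export
neutrality_test <- function(observed, null) {
  list(observed = observed,
       p_upper = empirical_p(observed, null, "upper"),
       p_lower = empirical_p(observed, null, "lower"),
       p_two_sided = empirical_p(observed, null, "two-sided"),
       ci95 = ci_bounds(null, 0.95),
       ci99 = ci_bounds(null, 0.99))
}
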
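## Rejection ABC with local-linear regression adjustment, model choice by
## acceptance ratios, and demographic calibration from reference loci.

#' Uniform prior specification
#'
#' Priors are uniform boxes, one per free parameter.
#'
#' @param ... named length-2 numeric vectors `c(lower, upper)`.
#' @return object of class `prior_spec` (named list).
#' @examples
#' prior_spec(C = c(0, 20), lambda_tract = c(50, 2000))
#' @export
prior_spec <- function(...) {
  spec <- list(...)
  if (length(spec) == 0 || is.null(names(spec)) || any(names(spec) == ""))
    stop("priors must be named")
  for (nm in names(spec)) {
    b <- spec[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop("prior for ", nm, " must be c(lower, upper) with lower < upper")
  }
  structure(spec, class = "prior_spec")
}

#' Draw parameters from uniform priors
#'
#' @param spec a [prior_spec()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return data.frame with one column per parameter, n rows.
#' @export
sample_priors <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  draws <- lapply(spec, function(b) stats::runif(n, b[1], b[2]))
  as.data.frame(draws)
}

#' Simulate the reference table for ABC
#'
#' Runs the duplicated-locus coalescent once per parameter row and records
#' the summary-statistic vector. Rows whose statistics contain undefined
#' values (e.g. Tajima's D with no segregating sites) are re-simulated with
#' fresh randomness so the table has no missing values.
#'
#' @param params data.frame of drawn parameters (columns named as
#'   [sim_params()] arguments, e.g. `C`, `lambda_tract`, `theta`).
#' @param fixed named list of fixed [sim_params()] arguments completing the
#'   model (sample sizes, L, theta, t_dup, ...).
#' @param stat_set character vector of summary-statistic names to keep.
#' @param seed optional integer seed.
#' @param max_resample maximum re-simulations per row.
#' @return object of class `sim_table`: list with `params` (data.frame),
#'   `stats` (matrix), `n_resampled`.
#' @export
run_simulations <- function(params, fixed, stat_set = abc_default_stats(),
                            seed = NULL, max_resample = 100) {
  if (!is.null(seed)) set.seed(seed)
  nrows <- nrow(params)
  stats_mat <- matrix(NA_real_, nrows, length(stat_set),
                      dimnames = list(NULL, stat_set))
  n_resampled <- 0L
  for (i in seq_len(nrows)) {
    args <- c(as.list(params[i, , drop = FALSE]), fixed)
    p <- do.call(sim_params, args)
    for (try in seq_len(max_resample)) {
      sv <- summary_vector(sim_once(p))
      row <- sv[stat_set]
      if (!anyNA(row)) break
      n_resampled <- n_resampled + 1L
    }
    if (anyNA(row))
      stop("replicate for row ", i, " kept producing undefined statistics")
    stats_mat[i, ] <- row
  }
  structure(list(params = params, stats = stats_mat,
                 n_resampled = n_resampled),
            class = "sim_table")
}

#' Default ABC statistic set
#'
#' Per-locus segregating sites, mean pairwise differences and Tajima's D,
#' plus the cross-locus shared, fixed and private polymorphism counts --
#' the counts most informative about interlocus gene conversion.
#'
#' @return character vector of statistic names.
#' @export
abc_default_stats <- function() {
  c("S_A", "S_B", "pi_total_A", "pi_total_B", "D_A", "D_B",
    "n_shared", "n_fixed", "n_private")
}

# standardize columns by their standard deviation across the table,
# dropping zero-variance statistics with a warning
standardize_stats <- function(stats_mat, observed) {
  sds <- apply(stats_mat, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep))
    warning("dropping zero-variance statistics: ",
            paste(colnames(stats_mat)[!keep], collapse = ", "))
  if (!any(keep)) stop("all statistics have zero variance")
  list(stats = sweep(stats_mat[, keep, drop = FALSE], 2, sds[keep], "/"),
       observed = observed[colnames(stats_mat)[keep]] / sds[keep],
       keep = keep)
}

#' Rejection step of ABC
#'
#' Standardizes each statistic by its standard deviation across the
#' reference table, computes Euclidean distances delta to the observed
#' vector, and retains the k simulations with the smallest delta (ties
#' broken by row index).
#'
#' @param observed named numeric vector of observed statistics (a
#'   [summary_vector()] or subset of one).
#' @param table a `sim_table` from [run_simulations()].
#' @param k number of simulations to retain.
#' @return object of class `abc_posterior`: retained parameter draws,
#'   their distances, the bandwidth (max retained delta) and the full
#'   distance vector.
#' @export
rejection <- function(observed, table, k) {
  stopifnot(inherits(table, "sim_table"), k >= 1, k <= nrow(table$stats))
  std <- standardize_stats(table$stats, observed)
  delta <- sqrt(rowSums(sweep(std$stats, 2, std$observed, "-")^2))
  ord <- order(delta)          # stable: ties broken by row index
  idx <- ord[seq_len(k)]
  structure(list(retained = table$params[idx, , drop = FALSE],
                 adjusted = NULL,
                 delta = delta[idx], index = idx,
                 bandwidth = max(delta[idx]),
                 stats_retained = table$stats[idx, colnames(std$stats),
                                              drop = FALSE],
                 observed = observed[colnames(std$stats)],
                 sds = apply(table$stats, 2, stats::sd)[colnames(std$stats)],
                 all_delta = delta),
            class = "abc_posterior")
}

#' Local-linear regression adjustment (Beaumont et al. 2002 style)
#'
#' Weighted local-linear regression of each retained parameter on the
#' standardized summary statistics, with Epanechnikov weights on the
#' rejection distances (bandwidth = largest retained distance). Each
#' retained draw is shifted by the fitted linear trend evaluated at the
#' observed statistics; adjusted draws are clamped to the prior support
#' when one is given. Falls back to the unadjusted draws with a warning if
#' the local design matrix is singular.
#'
#' @param post an `abc_posterior` from [rejection()].
#' @param prior optional [prior_spec()] providing support bounds.
#' @return the `abc_posterior` with an `adjusted` data.frame filled in.
#' @export
regression_adjust <- function(post, prior = NULL) {
  stopifnot(inherits(post, "abc_posterior"))
  X <- sweep(post$stats_retained, 2, post$sds, "/")
  xobs <- post$observed / post$sds
  Xc <- sweep(X, 2, xobs, "-")
  bw <- post$bandwidth
  w <- if (bw > 0) 1 - (post$delta / bw)^2 else rep(1, length(post$delta))
  w <- pmax(w, 1e-12)
  adj <- post$retained
  design <- cbind(1, Xc)
  ok <- tryCatch({
    fit <- stats::lm.wfit(design, as.matrix(post$retained), w)
    beta <- as.matrix(fit$coefficients)  # single-parameter fits drop dims
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    warning("singular regression design; returning unadjusted draws")
    post$adjusted <- post$retained
    return(post)
  }
  # statistics constant among the retained draws are inestimable (collinear
  # with the intercept); they contribute no local trend
  beta[is.na(beta)] <- 0
  # adjusted draw = draw - (fitted trend at sims) + (fitted trend at obs);
  # at the observed stats Xc = 0, so subtract Xc %*% slope
  slope <- beta[-1, , drop = FALSE]
  shift <- Xc %*% slope
  adjmat <- as.matrix(post$retained) - shift
  adj <- as.data.frame(adjmat)
  names(adj) <- names(post$retained)
  rownames(adj) <- NULL
  if (!is.null(prior)) {
    for (nm in intersect(names(adj), names(prior)))
      adj[[nm]] <- pmin(pmax(adj[[nm]], prior[[nm]][1]), prior[[nm]][2])
  }
  post$adjusted <- adj
  post
}

#' Posterior mode and credibility interval
#'
#' Mode is the argmax of a Gaussian kernel density (Silverman's bandwidth)
#' on a 512-point grid over the support; the 95% credibility interval is
#' the (2.5%, 97.5%) empirical quantiles of the draws.
#'
#' @param draws numeric vector of posterior draws (>= 50).
#' @param support optional `c(lower, upper)` grid limits (defaults to the
#'   range of the draws).
#' @param level credibility level (default 0.95).
#' @return named numeric vector `c(mode, ci_lower, ci_upper)`.
#' @export
posterior_summary <- function(draws, support = NULL, level = 0.95) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 50) stop("need at least 50 draws")
  alpha <- (1 - level) / 2
  ci <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE)
  if (stats::sd(draws) == 0) {
    mode <- draws[1]
  } else {
    if (is.null(support)) support <- range(draws)
    den <- stats::density(draws, bw = "nrd0", n = 512,
                          from = support[1], to = support[2])
    mode <- den$x[which.max(den$y)]
  }
  c(mode = mode, ci_lower = ci[1], ci_upper = ci[2])
}

#' ABC model choice by acceptance ratio
#'
#' Pools the reference tables of two models, standardizes the statistics
#' jointly, retains the k simulations closest to the observed vector, and
#' reports the Bayes factor of model 2 over model 1 as the ratio of
#' retained counts. If no model-1 simulation is retained the Bayes factor
#' is reported as a lower bound (> k).
#'
#' @param observed named numeric vector of observed statistics.
#' @param table_M1,table_M2 `sim_table`s with equal row counts.
#' @param k number of pooled simulations to retain.
#' @return list with `bf` (Bayes factor M2:M1), `n_M1`, `n_M2`,
#'   `lower_bound` (TRUE when the denominator was zero).
#' @export
model_choice <- function(observed, table_M1, table_M2, k) {
  stopifnot(k >= 1)
  if (nrow(table_M1$stats) != nrow(table_M2$stats))
    stop("model tables must have equal row counts")
  common <- intersect(colnames(table_M1$stats), colnames(table_M2$stats))
  pooled <- rbind(table_M1$stats[, common, drop = FALSE],
                  table_M2$stats[, common, drop = FALSE])
  std <- standardize_stats(pooled, observed)
  delta <- sqrt(rowSums(sweep(std$stats, 2, std$observed, "-")^2))
  idx <- order(delta)[seq_len(k)]
  n1 <- sum(idx <= nrow(table_M1$stats))
  n2 <- k - n1
  if (n1 == 0) {
    list(bf = Inf, n_M1 = 0L, n_M2 = n2, lower_bound = TRUE, bf_floor = k)
  } else {
    list(bf = n2 / n1, n_M1 = n1, n_M2 = n2, lower_bound = FALSE)
  }
}

#' Estimate the gene-conversion rate by ABC
#'
#' Convenience wrapper: draw from the priors, simulate the reference table,
#' run rejection and regression adjustment against the observed statistics,
#' and summarize the posterior of each free parameter.
#'
#' @param observed named numeric vector of observed statistics
#'   (a [summary_vector()]).
#' @param prior a [prior_spec()] over the free simulator parameters.
#' @param fixed named list of fixed [sim_params()] arguments.
#' @param n_sims number of simulations (production default 1e5; use fewer
#'   for exploratory runs).
#' @param k number retained.
#' @param stat_set statistic names used for the distance.
#' @param seed optional integer seed.
#' @return list with the `abc_posterior`, per-parameter
#'   [posterior_summary()] rows, and the reference table.
#' @export
abc_estimate <- function(observed, prior, fixed, n_sims = 1e5, k = 500,
                         stat_set = abc_default_stats(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- sample_priors(prior, n_sims)
  table <- run_simulations(draws, fixed, stat_set)
  post <- rejection(observed[stat_set], table, k)
  post <- regression_adjust(post, prior)
  summaries <- t(vapply(names(prior), function(nm)
    posterior_summary(post$adjusted[[nm]], support = prior[[nm]]),
    c(mode = 0, ci_lower = 0, ci_upper = 0)))
  list(posterior = post, summary = summaries, table = table)
}

#' Fit the expansion demography from reference loci
#'
#' Calibrates (theta, expansion factor f, expansion time t_exp) by ABC
#' against a panel of unlinked single-copy reference loci. The observed
#' statistics are the mean and variance across loci of (S, pi per site,
#' Tajima's D); each simulated dataset is the same number of independent
#' neutral single-locus coalescents under the drawn demography.
#'
#' @param ref_stats data.frame or matrix with one row per reference locus
#'   and columns `S`, `pi_site`, `D` (plus optional `n`, `L` per locus; a
#'   common `n`/`L` may instead be given via `n` and `L` arguments).
#' @param prior a [prior_spec()] over any of `theta`, `growth_factor`,
#'   `t_exp`.
#' @param n,L sample size and length used for loci without their own.
#' @param fixed named list of additional fixed [sim_params()] arguments
#'   (e.g. `t_exp` when only `theta` and `growth_factor` are free).
#' @param n_sims,k ABC settings.
#' @param seed optional integer seed.
#' @return list as in [abc_estimate()].
#' @export
fit_demography <- function(ref_stats, prior, n = 14, L = 500,
                           fixed = list(), n_sims = 2e4, k = 200,
                           seed = NULL) {
  ref_stats <- as.data.frame(ref_stats)
  if (nrow(ref_stats) < 2) stop("need at least two reference loci")
  if (!is.null(seed)) set.seed(seed)
  ns <- if ("n" %in% names(ref_stats)) ref_stats$n else rep(n, nrow(ref_stats))
  Ls <- if ("L" %in% names(ref_stats)) ref_stats$L else rep(L, nrow(ref_stats))
  obs <- demog_obs_vector(ref_stats[, c("S", "pi_site", "D")])
  draws <- sample_priors(prior, n_sims)
  stats_mat <- matrix(NA_real_, n_sims, 6,
                      dimnames = list(NULL, names(obs)))
  for (i in seq_len(n_sims)) {
    loci <- t(vapply(seq_along(ns), function(l) {
      args <- c(list(n_A = ns[l], n_B = 0, L = Ls[l], C = 0, t_dup = 100),
                fixed)
      for (nm in names(draws)) args[[nm]] <- draws[[nm]][i]
      r <- sim_once(do.call(sim_params, args))
      st <- locus_stats01(r$mat_A, Ls[l])
      c(S = unname(st["S"]), pi_site = unname(st["pi_site"]),
        D = unname(st["D"]))
    }, c(S = 0, pi_site = 0, D = 0)))
    stats_mat[i, ] <- demog_obs_vector(as.data.frame(loci))
  }
  table <- structure(list(params = draws, stats = stats_mat,
                          n_resampled = 0L), class = "sim_table")
  post <- rejection(obs, table, k)
  post <- regression_adjust(post, prior)
  summaries <- t(vapply(names(prior), function(nm)
    posterior_summary(post$adjusted[[nm]], support = prior[[nm]]),
    c(mode = 0, ci_lower = 0, ci_upper = 0)))
  list(posterior = post, summary = summaries, table = table)
}

# mean and variance across loci of (S, pi_site, D); loci with undefined D
# (no segregating sites) are dropped from the D moments, and a panel where
# every locus is monomorphic reports 0 for them
demog_obs_vector <- function(df) {
  out <- c(S_mean = mean(df$S), S_var = stats::var(df$S),
           pi_mean = mean(df$pi_site), pi_var = stats::var(df$pi_site),
           D_mean = mean(df$D, na.rm = TRUE),
           D_var = stats::var(df$D, na.rm = TRUE))
  out[!is.finite(out)] <- 0
  out
}
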
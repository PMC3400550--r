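#' Parameters for the duplicated-locus coalescent
#'
#' Bundles and validates the parameters of the structured coalescent for a
#' pair of recently duplicated loci exchanging sequence by interlocus gene
#' conversion, with an optional stepwise population expansion.
#'
#' Times are in units of 4N generations. `theta` and `C` are the population
#' mutation rate (4N mu) and population gene-conversion rate (4Nc) per site;
#' `C` is the rate at which a given site is covered by a conversion tract, so
#' the per-site marginal process between the two loci is exactly a two-island
#' migration model with rate `C`. Tract lengths are geometric with mean
#' `lambda_tract` (bp), started uniformly on the locus and truncated at the
#' locus end. `growth_factor` is the ratio of the current to the ancestral
#' population size (size changes instantaneously at `t_exp`); `t_dup` is the
#' duplication time, before which the second locus does not exist.
#'
#' @param n_A,n_B numbers of sampled haplotypes at locus A and locus B.
#' @param L sites per locus.
#' @param theta population mutation rate per site (4N mu).
#' @param C population gene-conversion rate per site (4Nc); 0 disables
#'   conversion.
#' @param lambda_tract mean conversion tract length in bp (>= 1).
#' @param t_dup duplication time in 4N generations.
#' @param growth_factor ratio f >= 1 of current to ancestral population size.
#' @param t_exp time of the instantaneous expansion, 4N generations.
#' @return an object of class `sim_params`.
#' @examples
#' p <- sim_params(n_A = 14, n_B = 9, L = 1000, theta = 0.0085, C = 1)
#' rep <- simulate(p, seed = 1)
#' ncol(rep$mat_A)
#' @export
sim_params <- function(n_A, n_B, L = 1000, theta = 0.0085, C = 0,
                       lambda_tract = 500, t_dup = 0.5,
                       growth_factor = 1, t_exp = 0) {
  stopifnot(n_A >= 0, n_B >= 0, n_A + n_B >= 2, L >= 1, t_dup > 0,
            growth_factor >= 1, t_exp >= 0)
  if (!is.finite(theta) || theta <= 0) stop("theta must be positive and finite")
  if (!is.finite(C) || C < 0) stop("C must be non-negative and finite")
  if (C > 0 && lambda_tract < 1)
    stop("lambda_tract must be >= 1 when C > 0")
  if (n_A + n_B > 64) stop("total sample size is limited to 64 haplotypes")
  structure(list(n_A = as.integer(n_A), n_B = as.integer(n_B),
                 L = as.integer(L), theta = theta, C = C,
                 lambda_tract = lambda_tract, t_dup = t_dup,
                 growth_factor = growth_factor, t_exp = t_exp),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Duplicated-locus coalescent parameters\n")
  cat(sprintf("  samples: n_A = %d, n_B = %d; L = %d sites/locus\n",
              x$n_A, x$n_B, x$L))
  cat(sprintf("  theta = %g, C = %g (tract mean %g bp)\n",
              x$theta, x$C, x$lambda_tract))
  cat(sprintf("  t_dup = %g, expansion f = %g at t_exp = %g (4N units)\n",
              x$t_dup, x$growth_factor, x$t_exp))
  invisible(x)
}

#' Simulate replicates of the duplicated-locus coalescent
#'
#' Runs the event-driven structured coalescent described in
#' [sim_params()]. Each replicate carries one binary haplotype matrix per
#' locus over a common set of mutated sites (homologous columns across
#' loci; ancestral state 0), plus the per-site time to the most recent
#' common ancestor of the full sample.
#'
#' Internally the sampler works in units of 2N generations (pairwise
#' coalescence rate 1, multiplied by `growth_factor` in the smaller
#' ancestral population); user-facing times in `object` are in 4N units and
#' converted on entry. Mutations are Poisson with rate theta/2 per site per
#' 2N generations on ancestral material, so a constant-size single locus
#' satisfies E[S] = theta * L * a_n. Each mutation gets a distinct uniform
#' site (collisions resampled).
#'
#' @param object a [sim_params()] object.
#' @param nsim number of replicates.
#' @param seed optional integer seed (`set.seed`) for reproducibility.
#' @param ... unused.
#' @return for `nsim = 1` a `sim_replicate` (list with `positions`, `mat_A`,
#'   `mat_B`, `tmrca`, `params`); otherwise a list of them.
#' @export
simulate.sim_params <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", nsim)
  for (i in seq_len(nsim)) reps[[i]] <- sim_once(object)
  if (nsim == 1) reps[[1]] else reps
}

sim_once <- function(p) {
  raw <- sim_duplicate_cpp(p$n_A, p$n_B, p$L, p$theta, p$C, p$lambda_tract,
                           2 * p$t_dup, p$growth_factor, 2 * p$t_exp,
                           max_events = 5e7)
  mat <- raw$mat
  structure(list(positions = raw$positions,
                 mat_A = mat[seq_len(p$n_A), , drop = FALSE],
                 mat_B = if (p$n_B > 0) {
                   mat[p$n_A + seq_len(p$n_B), , drop = FALSE]
                 } else {
                   matrix(0L, 0, ncol(mat))
                 },
                 tmrca = raw$tmrca, params = p),
            class = "sim_replicate")
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat(sprintf("sim_replicate: %d mutated sites, n_A = %d, n_B = %d, L = %d\n",
              length(x$positions), nrow(x$mat_A), nrow(x$mat_B),
              x$params$L))
  invisible(x)
}

#' Closed-form pairwise coalescence times under conversion-as-migration
#'
#' For a single site in a constant-size population with an infinitely old
#' duplication, the residence of a pair of lineages follows a two-state
#' Markov chain: in the same locus they coalesce at rate 1 and separate at
#' rate `C`; in different loci they reunite at rate `C`. Solving the chain
#' gives E[T_same] = 2 and E[T_diff] = 2 + 1/C in units of 2N generations.
#' This is the analytic oracle for the simulator's per-site marginal
#' behaviour.
#'
#' @param C population gene-conversion rate per site (> 0).
#' @return named numeric vector `c(E_T_same, E_T_diff)`, 2N units.
#' @examples
#' two_lineage_oracle(1)  # c(2, 3)
#' @export
two_lineage_oracle <- function(C) {
  if (!is.finite(C) || C <= 0) stop("C must be positive")
  c(E_T_same = 2, E_T_diff = 2 + 1 / C)
}

#' Serialize a replicate to ms-style text
#'
#' One block per locus with `segsites:` and `positions:` lines followed by
#' 0/1 haplotype rows, in the style of Hudson's ms. Positions are printed as
#' 1-based integer site indices (the simulator's discrete infinite-sites
#' map); both loci share the same homologous column set.
#'
#' @param replicate a `sim_replicate`.
#' @return a single character string.
#' @seealso [parse_ms_text()]
#' @export
to_ms_text <- function(replicate) {
  stopifnot(inherits(replicate, "sim_replicate"))
  block <- function(mat, positions) {
    s <- ncol(mat)
    lines <- c("//", paste0("segsites: ", s))
    if (s > 0) {
      lines <- c(lines, paste0("positions: ", paste(positions, collapse = " ")),
                 apply(mat, 1, paste, collapse = ""))
    }
    lines
  }
  paste(c(block(replicate$mat_A, replicate$positions),
          block(replicate$mat_B, replicate$positions), ""),
        collapse = "\n")
}

#' Parse ms-style text produced by [to_ms_text()]
#'
#' @param text character string with two locus blocks.
#' @return list with `positions`, `mat_A`, `mat_B`.
#' @export
parse_ms_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- which(lines == "//")
  if (length(starts) != 2) stop("expected two locus blocks")
  read_block <- function(from, to) {
    blk <- lines[from:to]
    s <- as.integer(sub("segsites: ", "", blk[2], fixed = TRUE))
    if (s == 0) {
      list(positions = integer(0), mat = matrix(0L, 0, 0))
    } else {
      pos <- as.integer(strsplit(sub("positions: ", "", blk[3]), " ")[[1]])
      rows <- blk[-(1:3)]
      rows <- rows[nzchar(rows)]
      mat <- do.call(rbind, lapply(strsplit(rows, ""),
                                   function(r) as.integer(r)))
      list(positions = pos, mat = mat)
    }
  }
  a <- read_block(starts[1], starts[2] - 1)
  b <- read_block(starts[2], length(lines))
  list(positions = a$positions, mat_A = a$mat, mat_B = b$mat)
}
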
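## Summary statistics: diversity, neutrality tests, differentiation,
## cross-locus polymorphism classification, sliding windows.
##
## All statistics use pairwise deletion for missing data (gaps and N), the
## convention of the standard desktop tools for Sanger allele panels, and
## are invariant to the row order of the alignment.

# encode an alignment as an integer matrix with NA for missing
aln_encode <- function(aln) {
  mat <- unclass(aln)
  code <- match(mat, c("A", "C", "G", "T"))
  dim(code) <- dim(mat)
  rownames(code) <- rownames(mat)
  code
}

# per-column allele counts -> sum over columns of discordant non-missing
# pairs, plus bookkeeping used by several statistics
col_pair_counts <- function(code) {
  apply(code, 2, function(col) {
    col <- col[!is.na(col)]
    m <- length(col)
    if (m < 2) return(c(diff = 0, pairs = 0, nalleles = if (m == 0) 0 else 1))
    tab <- tabulate(col, nbins = 4)
    c(diff = (m * (m - 1) - sum(tab * (tab - 1))) / 2,
      pairs = m * (m - 1) / 2,
      nalleles = sum(tab > 0))
  })
}

harmonic <- function(n, power = 1) sum(1 / seq_len(n - 1)^power)

#' Nucleotide diversity (mean pairwise differences)
#'
#' `pi_total` is the mean number of pairwise differences over all sequence
#' pairs (missing sites deleted pairwise); `pi_site` divides by the number
#' of columns with at least two non-missing alleles.
#'
#' @param aln an [alignment()].
#' @return named numeric vector `c(pi_total, pi_site)`.
#' @export
pi_diversity <- function(aln) {
  n <- nrow(aln)
  if (n < 2) stop("sample-size error: need at least 2 sequences")
  cc <- col_pair_counts(aln_encode(aln))
  npairs <- n * (n - 1) / 2
  pi_total <- sum(cc["diff", ]) / npairs
  L_eff <- sum(cc["pairs", ] > 0)
  c(pi_total = pi_total,
    pi_site = if (L_eff > 0) pi_total / L_eff else 0)
}

# number of segregating columns
seg_sites <- function(aln) {
  cc <- col_pair_counts(aln_encode(aln))
  sum(cc["nalleles", ] > 1)
}

#' Watterson's theta per site
#'
#' S / (a_n * L_eff) with a_n the harmonic number of n - 1 and L_eff the
#' number of columns with at least two non-missing alleles.
#'
#' @param aln an [alignment()].
#' @return numeric scalar.
#' @export
watterson <- function(aln) {
  n <- nrow(aln)
  if (n < 2) stop("sample-size error: need at least 2 sequences")
  cc <- col_pair_counts(aln_encode(aln))
  S <- sum(cc["nalleles", ] > 1)
  L_eff <- sum(cc["pairs", ] > 0)
  if (S == 0 || L_eff == 0) return(0)
  S / (harmonic(n) * L_eff)
}

# Tajima (1989) D from sample size, segregating sites and mean pairwise
# differences; NA when S = 0 (undefined, the DnaSP convention)
tajima_d_core <- function(n, S, pi_total) {
  if (S == 0) return(NA_real_)
  a1 <- harmonic(n)
  a2 <- harmonic(n, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's D
#'
#' Normalized difference between pairwise-diversity-based and
#' segregating-sites-based estimates of the population mutation rate.
#' Positive values indicate an excess of intermediate-frequency variants
#' (the signature of balancing selection), negative values an excess of
#' rare variants. Returns NA when there are no segregating sites.
#'
#' @param aln an [alignment()].
#' @return numeric scalar (NA if undefined).
#' @export
tajimas_d <- function(aln) {
  n <- nrow(aln)
  if (n < 2) stop("sample-size error: need at least 2 sequences")
  tajima_d_core(n, seg_sites(aln), pi_diversity(aln)[["pi_total"]])
}

#' Fu and Li's D (outgroup-polarized)
#'
#' Contrasts the total number of mutations with the number of derived
#' singletons (external-branch mutations), polarized by an outgroup
#' sequence, using the variance constants of Fu and Li (1993). Only
#' biallelic ingroup columns where the outgroup carries one of the two
#' alleles are informative; columns with a missing or third-state outgroup
#' are excluded.
#'
#' @param aln an [alignment()] of the ingroup.
#' @param outgroup a single sequence (character string or one-row
#'   alignment) aligned to the same coordinates.
#' @return numeric scalar (NA if no informative mutations).
#' @export
fu_li_d <- function(aln, outgroup) {
  n <- nrow(aln)
  if (n < 3) stop("sample-size error: need at least 3 sequences")
  if (is.null(outgroup))
    stop("unpolarizable data: an outgroup sequence is required")
  og <- if (inherits(outgroup, "alignment")) unclass(outgroup)[1, ]
        else strsplit(toupper(outgroup), "")[[1]]
  if (length(og) != ncol(aln))
    stop("coordinate error: outgroup length differs from alignment")
  code <- aln_encode(aln)
  ogc <- match(og, c("A", "C", "G", "T"))
  eta <- 0L
  eta_e <- 0L
  for (j in seq_len(ncol(code))) {
    if (is.na(ogc[j])) next
    col <- code[!is.na(code[, j]), j]
    tab <- tabulate(col, nbins = 4)
    present <- which(tab > 0)
    if (length(present) != 2) next
    if (!(ogc[j] %in% present)) next  # outgroup carries a third state
    derived <- setdiff(present, ogc[j])
    eta <- eta + 1L
    if (tab[derived] == 1) eta_e <- eta_e + 1L
  }
  if (eta == 0) return(NA_real_)
  a_n <- harmonic(n)
  b_n <- harmonic(n, 2)
  c_n <- if (n == 2) 1 else 2 * (n * a_n - 2 * (n - 1)) / ((n - 1) * (n - 2))
  v_d <- 1 + a_n^2 / (b_n + a_n^2) * (c_n - (n + 1) / (n - 1))
  u_d <- a_n - 1 - v_d
  (eta - a_n * eta_e) / sqrt(u_d * eta + v_d * eta^2)
}

#' Hudson's F_ST between two groups
#'
#' The Hudson, Slatkin & Maddison (1992) estimator 1 - Hw/Hb, where Hw is
#' the mean within-group number of pairwise differences (pooled over both
#' groups) and Hb the mean between-group number. The value is at most 1 and
#' may be negative.
#'
#' @param aln an [alignment()].
#' @param labels vector of two group labels, one per sequence.
#' @return numeric scalar (NA if Hb = 0).
#' @export
fst_two_groups <- function(aln, labels) {
  stopifnot(length(labels) == nrow(aln))
  groups <- unique(labels)
  if (length(groups) != 2) stop("grouping error: need exactly two groups")
  idx1 <- which(labels == groups[1])
  idx2 <- which(labels == groups[2])
  if (length(idx1) < 1 || length(idx2) < 1)
    stop("grouping error: empty group")
  code <- aln_encode(aln)
  pair_sum <- function(rows1, rows2, within) {
    tot <- 0
    npair <- 0
    for (i in rows1) {
      js <- if (within) rows2[rows2 > i] else rows2
      for (j in js) {
        ok <- !is.na(code[i, ]) & !is.na(code[j, ])
        tot <- tot + sum(code[i, ok] != code[j, ok])
        npair <- npair + 1
      }
    }
    c(tot, npair)
  }
  w1 <- pair_sum(idx1, idx1, TRUE)
  w2 <- pair_sum(idx2, idx2, TRUE)
  b <- pair_sum(idx1, idx2, FALSE)
  if ((w1[2] + w2[2]) == 0)
    stop("grouping error: need at least one within-group pair")
  hw <- (w1[1] + w2[1]) / (w1[2] + w2[2])
  hb <- b[1] / b[2]
  if (hb == 0) return(if (hw == 0) 0 else NA_real_)  # no variation at all
  1 - hw / hb
}

#' Classify polymorphisms across two paralogous loci
#'
#' For each homologous column (shared coordinates), classifies it as
#' shared (segregating in both loci), private to A or B (segregating in
#' exactly one), or a fixed difference (monomorphic in both with different
#' states). Derived states are polarized by the outgroup; columns where the
#' outgroup is missing, or that are not biallelic over the pooled sample,
#' are excluded. Derived-allele frequency spectra are returned per class
#' (shared: pooled derived count; private: count within the segregating
#' locus).
#'
#' @param aln_A,aln_B [alignment()]s on homologous coordinates.
#' @param outgroup outgroup sequence (string or one-row alignment).
#' @return list of class `shared_private_spectrum`: counts `n_shared`,
#'   `n_private_A`, `n_private_B`, `n_fixed`; spectra `sfs_shared`,
#'   `sfs_private_A`, `sfs_private_B`; and per-class column positions.
#' @export
classify_cross_locus <- function(aln_A, aln_B, outgroup) {
  if (ncol(aln_A) != ncol(aln_B))
    stop("coordinate error: loci have different alignment lengths")
  og <- if (inherits(outgroup, "alignment")) unclass(outgroup)[1, ]
        else strsplit(toupper(outgroup), "")[[1]]
  if (length(og) != ncol(aln_A))
    stop("coordinate error: outgroup length differs from alignment")
  ca <- aln_encode(aln_A)
  cb <- aln_encode(aln_B)
  ogc <- match(og, c("A", "C", "G", "T"))
  nA <- nrow(ca)
  nB <- nrow(cb)
  cls <- character(ncol(ca))
  dcount <- integer(ncol(ca))
  for (j in seq_len(ncol(ca))) {
    if (is.na(ogc[j])) next
    a <- ca[!is.na(ca[, j]), j]
    b <- cb[!is.na(cb[, j]), j]
    if (length(a) == 0 || length(b) == 0) next
    tab <- tabulate(c(a, b), nbins = 4)
    present <- which(tab > 0)
    if (length(present) > 2) next          # not biallelic over the pool
    segA <- length(unique(a)) > 1
    segB <- length(unique(b)) > 1
    if (!segA && !segB) {
      if (a[1] != b[1]) cls[j] <- "fixed"
      next
    }
    if (length(present) == 2 && ogc[j] %in% present) {
      derived <- setdiff(present, ogc[j])
      dc_a <- sum(a == derived)
      dc_b <- sum(b == derived)
    } else {
      dc_a <- dc_b <- NA_integer_          # unpolarizable; counted, no SFS
    }
    if (segA && segB) { cls[j] <- "shared"; dcount[j] <- dc_a + dc_b }
    else if (segA) { cls[j] <- "private_A"; dcount[j] <- dc_a }
    else { cls[j] <- "private_B"; dcount[j] <- dc_b }
  }
  sfs <- function(which_cls, nmax) {
    counts <- dcount[cls == which_cls]
    counts <- counts[!is.na(counts) & counts > 0]
    tabulate(counts, nbins = nmax)
  }
  structure(list(
    n_shared = sum(cls == "shared"),
    n_private_A = sum(cls == "private_A"),
    n_private_B = sum(cls == "private_B"),
    n_fixed = sum(cls == "fixed"),
    sfs_shared = sfs("shared", nA + nB),
    sfs_private_A = sfs("private_A", nA),
    sfs_private_B = sfs("private_B", nB),
    positions = list(shared = which(cls == "shared"),
                     private_A = which(cls == "private_A"),
                     private_B = which(cls == "private_B"),
                     fixed = which(cls == "fixed"))),
    class = "shared_private_spectrum")
}

#' @export
print.shared_private_spectrum <- function(x, ...) {
  cat(sprintf("cross-locus polymorphisms: %d shared, %d private-A, %d private-B, %d fixed\n",
              x$n_shared, x$n_private_A, x$n_private_B, x$n_fixed))
  invisible(x)
}

#' Sliding-window statistic
#'
#' Evaluates a per-alignment statistic in windows `[start, start + window)`
#' advancing by `step`. Windows where the statistic is undefined are
#' returned as NA with `defined = FALSE`.
#'
#' @param aln an [alignment()].
#' @param stat a function taking an alignment, or one of "pi_site",
#'   "pi_total", "tajimas_d", "watterson", "S".
#' @param window,step window length and step in alignment columns.
#' @return data.frame with `start`, `end`, `mid`, `value`, `defined`.
#' @export
sliding <- function(aln, stat = "tajimas_d", window = 100, step = 25) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  L <- ncol(aln)
  if (window > L) stop("window exceeds alignment length")
  f <- if (is.function(stat)) stat else switch(
    stat,
    pi_site = function(a) pi_diversity(a)[["pi_site"]],
    pi_total = function(a) pi_diversity(a)[["pi_total"]],
    tajimas_d = tajimas_d,
    watterson = watterson,
    S = seg_sites,
    stop("unknown statistic: ", stat))
  starts <- seq(1, L - window + 1, by = step)
  vals <- vapply(starts, function(s) {
    sub <- unclass(aln)[, s:(s + window - 1), drop = FALSE]
    class(sub) <- c("alignment", class(sub))
    as.numeric(f(sub))
  }, 0)
  data.frame(start = starts, end = starts + window - 1,
             mid = starts + (window - 1) / 2, value = vals,
             defined = !is.na(vals))
}

## ---- summary vectors (the ABC statistic bundle) ----

# per-locus stats from a 0/1 haplotype matrix (no missing data);
# all L sites count toward per-site scaling
locus_stats01 <- function(mat, L) {
  n <- nrow(mat)
  cnt <- colSums(mat)
  seg <- cnt > 0 & cnt < n
  S <- sum(seg)
  pi_total <- if (n >= 2) sum(cnt * (n - cnt)) / (n * (n - 1) / 2) else NA
  c(S = S, pi_total = pi_total, pi_site = pi_total / L,
    thetaW = if (n >= 2) S / (harmonic(n) * L) else NA,
    D = if (n >= 2) tajima_d_core(n, S, pi_total) else NA)
}

#' Summary-statistic vector for ABC
#'
#' Computes the per-locus statistics (S, pi, Watterson's theta, Tajima's D)
#' and the cross-locus polymorphism counts (shared, private, fixed) from
#' either a simulated replicate or a pair of observed alignments. This is
#' the statistic bundle fed to the ABC machinery.
#'
#' @param x a `sim_replicate`, or a list `list(aln_A =, aln_B =)` of
#'   [alignment()]s.
#' @param outgroup outgroup sequence (required for observed alignments to
#'   polarize the cross-locus classification; ignored for replicates where
#'   the ancestral state is 0 by construction).
#' @param ... unused.
#' @return named numeric vector of class `summary_vector`.
#' @export
summary_vector <- function(x, outgroup = NULL, ...) {
  UseMethod("summary_vector")
}

#' @export
summary_vector.sim_replicate <- function(x, outgroup = NULL, ...) {
  L <- x$params$L
  nA <- nrow(x$mat_A)
  nB <- nrow(x$mat_B)
  sa <- locus_stats01(x$mat_A, L)
  sb <- if (nB >= 2) locus_stats01(x$mat_B, L) else
    c(S = 0, pi_total = 0, pi_site = 0, thetaW = 0, D = NA)
  cntA <- colSums(x$mat_A)
  cntB <- if (nB > 0) colSums(x$mat_B) else integer(length(cntA))
  segA <- cntA > 0 & cntA < nA
  segB <- nB > 0 & cntB > 0 & cntB < nB
  shared <- segA & segB
  privA <- segA & !segB
  privB <- segB & !segA
  fixed <- (cntA == 0 & nB > 0 & cntB == nB) | (cntA == nA & cntB == 0)
  out <- c(S_A = unname(sa["S"]), S_B = unname(sb["S"]),
           pi_total_A = unname(sa["pi_total"]),
           pi_total_B = unname(sb["pi_total"]),
           pi_site_A = unname(sa["pi_site"]),
           pi_site_B = unname(sb["pi_site"]),
           thetaW_A = unname(sa["thetaW"]), thetaW_B = unname(sb["thetaW"]),
           D_A = unname(sa["D"]), D_B = unname(sb["D"]),
           n_shared = sum(shared), n_private_A = sum(privA),
           n_private_B = sum(privB), n_private = sum(privA) + sum(privB),
           n_fixed = sum(fixed))
  class(out) <- c("summary_vector", class(out))
  out
}

#' @export
summary_vector.list <- function(x, outgroup = NULL, ...) {
  stopifnot(!is.null(x$aln_A), !is.null(x$aln_B))
  sa <- pi_diversity(x$aln_A)
  sb <- pi_diversity(x$aln_B)
  cl <- if (!is.null(outgroup)) {
    classify_cross_locus(x$aln_A, x$aln_B, outgroup)
  } else {
    list(n_shared = NA, n_private_A = NA, n_private_B = NA, n_fixed = NA)
  }
  out <- c(S_A = seg_sites(x$aln_A), S_B = seg_sites(x$aln_B),
           pi_total_A = unname(sa["pi_total"]),
           pi_total_B = unname(sb["pi_total"]),
           pi_site_A = unname(sa["pi_site"]),
           pi_site_B = unname(sb["pi_site"]),
           thetaW_A = watterson(x$aln_A), thetaW_B = watterson(x$aln_B),
           D_A = tajimas_d(x$aln_A), D_B = tajimas_d(x$aln_B),
           n_shared = cl$n_shared, n_private_A = cl$n_private_A,
           n_private_B = cl$n_private_B,
           n_private = cl$n_private_A + cl$n_private_B,
           n_fixed = cl$n_fixed)
  class(out) <- c("summary_vector", class(out))
  out
}
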
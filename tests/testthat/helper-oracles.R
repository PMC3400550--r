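# Brute-force oracles and fixture builders used across the test files.
# Oracles recompute statistics by direct enumeration, independently of the
# package's column-counting implementations.

random_alignment <- function(n, L, missing_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  mat <- matrix(rep(anc, each = n), nrow = n)
  # sprinkle mutations column by column
  for (j in seq_len(L)) {
    k <- sample(0:2, 1, prob = c(0.5, 0.35, 0.15))
    if (k > 0) {
      rows <- sample(n, sample(seq_len(n - 1), 1))
      mat[rows, j] <- sample(setdiff(bases, anc[j]), 1)
      if (k == 2) {
        rows2 <- sample(setdiff(seq_len(n), rows), 1)
        mat[rows2, j] <- sample(setdiff(bases, mat[c(rows[1]), j]), 1)
      }
    }
  }
  if (missing_prob > 0)
    mat[matrix(runif(n * L) < missing_prob, n, L)] <- "-"
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  alignment(mat)
}

# mean pairwise differences by direct pair enumeration (pairwise deletion)
bf_pi_total <- function(aln) {
  m <- unclass(aln)
  m[m %in% c("-", "N")] <- NA
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      tot <- tot + sum(m[i, ok] != m[j, ok])
    }
  }
  tot / (n * (n - 1) / 2)
}

bf_seg_sites <- function(aln) {
  m <- unclass(aln)
  m[m %in% c("-", "N")] <- NA
  sum(apply(m, 2, function(col) length(unique(na.omit(col))) > 1))
}

bf_snp_positions <- function(aln) {
  m <- unclass(aln)
  m[m %in% c("-", "N")] <- NA
  which(apply(m, 2, function(col) length(unique(na.omit(col))) == 2))
}

# Hudson F_ST by explicit pair enumeration over difference counts
bf_fst <- function(aln, labels) {
  m <- unclass(aln)
  m[m %in% c("-", "N")] <- NA
  dif <- function(i, j) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    sum(m[i, ok] != m[j, ok])
  }
  g <- unique(labels)
  hw <- c()
  hb <- c()
  for (i in seq_len(nrow(m) - 1)) {
    for (j in seq(i + 1, nrow(m))) {
      if (labels[i] == labels[j]) hw <- c(hw, dif(i, j))
      else hb <- c(hb, dif(i, j))
    }
  }
  1 - mean(hw) / mean(hb)
}

# Fu & Li's D recomputed from scratch (derived-singleton count + the 1993
# variance constants); serves as a regression guard on the implementation
bf_fu_li_d <- function(aln, outgroup) {
  m <- unclass(aln)
  og <- strsplit(outgroup, "")[[1]]
  n <- nrow(m)
  eta <- 0
  eta_e <- 0
  for (j in seq_len(ncol(m))) {
    if (!og[j] %in% c("A", "C", "G", "T")) next
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    al <- unique(col)
    if (length(al) != 2 || !og[j] %in% al) next
    der <- setdiff(al, og[j])
    eta <- eta + 1
    if (sum(col == der) == 1) eta_e <- eta_e + 1
  }
  if (eta == 0) return(NA_real_)
  a_n <- sum(1 / seq_len(n - 1))
  b_n <- sum(1 / seq_len(n - 1)^2)
  c_n <- if (n == 2) 1 else 2 * (n * a_n - 2 * (n - 1)) / ((n - 1) * (n - 2))
  v_d <- 1 + a_n^2 / (b_n + a_n^2) * (c_n - (n + 1) / (n - 1))
  u_d <- a_n - 1 - v_d
  (eta - a_n * eta_e) / sqrt(u_d * eta + v_d * eta^2)
}

# tiny deterministic alignment from explicit strings
aln_from <- function(...) {
  s <- c(...)
  if (is.null(names(s))) names(s) <- sprintf("s%02d", seq_along(s))
  alignment(s)
}
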
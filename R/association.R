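## SNP-phenotype association: general linear model per marker with a
## minor-allele-frequency filter and Bonferroni correction.

#' Filter markers by minor-allele frequency
#'
#' Retains columns with MAF strictly greater than the threshold.
#'
#' @param snps a `snp_matrix` from [snp_table()].
#' @param maf_threshold frequency threshold in [0, 0.5]; default 0.25.
#' @return a filtered `snp_matrix`.
#' @export
filter_markers <- function(snps, maf_threshold = 0.25) {
  stopifnot(inherits(snps, "snp_matrix"),
            maf_threshold >= 0, maf_threshold <= 0.5)
  keep <- snps$maf > maf_threshold
  structure(list(positions = snps$positions[keep],
                 geno = snps$geno[, keep, drop = FALSE],
                 maf = snps$maf[keep],
                 major = snps$major[keep], minor = snps$minor[keep]),
            class = "snp_matrix")
}

#' Single-marker general linear model
#'
#' Ordinary least squares of a binary phenotype on a {0,1} genotype:
#' R-squared is the model sum of squares over the total, and the p-value
#' comes from the F(1, n-2) distribution. Pairs with a missing genotype or
#' phenotype are dropped. Constant genotype or phenotype gives an undefined
#' (flagged) result rather than an error.
#'
#' @param genotype numeric vector coded {0, 1} (NA = missing).
#' @param phenotype numeric/logical binary vector.
#' @return list with `r2`, `p`, `n_used`, `defined`.
#' @export
glm_assoc <- function(genotype, phenotype) {
  ok <- !is.na(genotype) & !is.na(phenotype)
  g <- as.numeric(genotype[ok])
  y <- as.numeric(phenotype[ok])
  n <- length(g)
  if (n < 3 || stats::var(g) == 0 || stats::var(y) == 0)
    return(list(r2 = NA_real_, p = NA_real_, n_used = n, defined = FALSE))
  r2 <- stats::cor(g, y)^2
  fstat <- r2 * (n - 2) / (1 - r2)
  p <- if (r2 >= 1) 0 else stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  list(r2 = r2, p = p, n_used = n, defined = TRUE)
}

#' Genome scan: GLM association at every marker
#'
#' Runs [glm_assoc()] at each marker of a (typically MAF-filtered) SNP
#' matrix, Bonferroni-corrects over the number of markers actually tested,
#' and flags significance at the corrected 0.05 and 0.01 levels. Raw
#' p-values are reported alongside the corrected ones.
#'
#' @param snps a `snp_matrix`.
#' @param phenotype binary phenotype vector, one entry per allele
#'   (row of `snps$geno`); NA entries are dropped per marker.
#' @return data.frame sorted by position with columns `position`, `r2`,
#'   `p`, `p_bonferroni`, `n_used`, `minor`, `maf`, `sig05`, `sig01`,
#'   `defined`.
#' @export
assoc_scan <- function(snps, phenotype) {
  stopifnot(inherits(snps, "snp_matrix"),
            length(phenotype) == nrow(snps$geno))
  m <- length(snps$positions)
  rows <- lapply(seq_len(m), function(j) {
    a <- glm_assoc(snps$geno[, j], phenotype)
    data.frame(position = snps$positions[j], r2 = a$r2, p = a$p,
               n_used = a$n_used, minor = snps$minor[j], maf = snps$maf[j],
               defined = a$defined)
  })
  out <- if (m > 0) do.call(rbind, rows) else
    data.frame(position = integer(0), r2 = numeric(0), p = numeric(0),
               n_used = integer(0), minor = character(0), maf = numeric(0),
               defined = logical(0))
  m_tested <- sum(out$defined)
  out$p_bonferroni <- pmin(1, out$p * m_tested)
  out$sig05 <- !is.na(out$p_bonferroni) & out$p_bonferroni < 0.05
  out$sig01 <- !is.na(out$p_bonferroni) & out$p_bonferroni < 0.01
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  out[, c("position", "r2", "p", "p_bonferroni", "n_used", "minor",
          "maf", "sig05", "sig01", "defined")]
}

#' Encode phenotype classes as binary contrasts
#'
#' The panel's four phenotype classes are: I = protein not accumulated
#' (pseudogenes), II = protease not inhibited by the pathogen effector and
#' no hypersensitive response, III = inhibited with attenuated HR, IV =
#' inhibited with strong HR. Two binary contrasts are analysed: effector
#' sensitivity (class II vs III+IV) and HR strength (III vs IV); class I
#' alleles are excluded (NA) from both.
#'
#' @param classes character or factor vector of classes "I".."IV".
#' @param contrast "sensitivity" (II = 1 vs III/IV = 0) or "hr"
#'   (III = 1 vs IV = 0).
#' @return numeric vector of 0/1 with NA for excluded classes.
#' @export
phenotype_contrast <- function(classes, contrast = c("sensitivity", "hr")) {
  contrast <- match.arg(contrast)
  cls <- as.character(classes)
  bad <- !cls %in% c("I", "II", "III", "IV") & !is.na(cls)
  if (any(bad)) stop("unknown phenotype class: ",
                     paste(unique(cls[bad]), collapse = ", "))
  if (contrast == "sensitivity") {
    ifelse(cls == "II", 1, ifelse(cls %in% c("III", "IV"), 0, NA))
  } else {
    ifelse(cls == "III", 1, ifelse(cls == "IV", 0, NA))
  }
}
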
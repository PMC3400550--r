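## Synthetic allele-panel generator: produces FASTA-ready alignments with
## the statistical structure the pipeline assumes (two paralogous loci,
## a balanced intronic sequence-type dimorphism, pseudogene alleles, an
## outgroup carrying ancestral states, and planted causal variants), with
## the generating truth recorded for closure testing.

BASES <- c("A", "C", "G", "T")

#' Deterministic base ORF + intron sequence
#'
#' Builds a synthetic coding sequence with one intron and a valid reading
#' frame: `n_codons` non-stop codons, a single terminal stop (TAA), and an
#' intron of `intron_len` bp inserted after `exon1_len` coding bases. The
#' same arguments always yield the same sequence.
#'
#' @param n_codons number of codons before the terminal stop.
#' @param intron_len intron length in bp.
#' @param exon1_len coding bases before the intron.
#' @return list with `seq` (character vector), `orf_start`,
#'   `intron_interval`, `L`.
#' @export
base_orf_sequence <- function(n_codons = 332, intron_len = 110,
                              exon1_len = 450) {
  stopifnot(exon1_len %% 3 == 0, exon1_len < 3 * n_codons)
  codons <- expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE)
  codons <- apply(codons, 1, paste, collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  # deterministic pseudo-random codon choice, independent of the session RNG
  idx <- (seq_len(n_codons) * 37 + 11) %% length(codons) + 1
  coding <- c(strsplit(paste(codons[idx], collapse = ""), "")[[1]], "T", "A", "A")
  intron <- BASES[(seq_len(intron_len) * 13 + 5) %% 4 + 1]
  intron[1:2] <- c("G", "T")                     # canonical splice donor
  intron[(intron_len - 1):intron_len] <- c("A", "G")
  seq <- c(coding[seq_len(exon1_len)], intron,
           coding[seq(exon1_len + 1, length(coding))])
  list(seq = seq, orf_start = 1L,
       intron_interval = c(exon1_len + 1L, exon1_len + intron_len),
       L = length(seq))
}

#' Generate a synthetic duplicated gene family
#'
#' Runs the duplicated-locus coalescent, maps the binary haplotypes onto a
#' base nucleotide sequence (0 = base state, 1 = a drawn alternative), and
#' overlays the features the analysis expects in real panels:
#'
#' * a balanced intronic dimorphism: all intronic variation is replaced by
#'   two haplotypes diverged at `type_divergence` per site, assigned to
#'   alleles at intermediate frequency within each locus (the simulator is
#'   neutral; the dimorphism emulating long-term balancing selection is
#'   overlaid deterministically);
#' * `pseudogene_count` alleles made non-functional by a 1-bp deletion
#'   (frameshift) or an in-frame premature stop codon;
#' * an outgroup sequence carrying the ancestral (base) state everywhere.
#'
#' @param params a [sim_params()]; defaults mirror the study panel
#'   (14 + 9 alleles, ~1 kb, theta 0.0085, conversion rate about 1).
#' @param type_divergence per-site divergence between the two intronic
#'   sequence types.
#' @param type_freq frequency of sequence type 2 within each locus.
#' @param pseudogene_count number of pseudogene alleles to inject.
#' @param base optional result of [base_orf_sequence()].
#' @param seed integer seed; the truth plus seed fully determine the output.
#' @return list with `aln_A`, `aln_B` ([alignment()]s), `outgroup`
#'   (character string), and `truth` (class `synthetic_truth`).
#' @export
generate_gene_family <- function(params = sim_params(n_A = 14, n_B = 9,
                                                     L = 1109,
                                                     theta = 0.0085, C = 1,
                                                     lambda_tract = 500,
                                                     t_dup = 0.5),
                                 type_divergence = 0.05, type_freq = 0.4,
                                 pseudogene_count = 2, base = NULL,
                                 seed = 1) {
  if (is.null(base)) base <- base_orf_sequence()
  if (base$L != params$L)
    stop("params$L must equal the base sequence length (", base$L, ")")
  ii <- base$intron_interval
  if (ii[2] > params$L) stop("intron interval outside L")
  nA <- params$n_A
  nB <- params$n_B
  if (pseudogene_count < 0 || pseudogene_count > nA + nB)
    stop("pseudogene_count must be in [0, n_A + n_B]")
  set.seed(seed)
  rep <- sim_once(params)

  icols <- seq(ii[1], ii[2])
  keep <- !(rep$positions %in% icols)     # intron variation is overlaid
  positions <- rep$positions[keep]
  hap <- rbind(rep$mat_A[, keep, drop = FALSE],
               rep$mat_B[, keep, drop = FALSE])
  # alternative bases for exonic sites must not create in-frame stop codons
  # (pseudogene status is controlled explicitly below, not by mutation noise)
  alt <- vapply(positions, function(s) {
    cands <- setdiff(BASES, base$seq[s])
    cpos <- if (s < ii[1]) s else s - (ii[2] - ii[1] + 1)
    cod <- (cpos - 1) %/% 3
    cpos_cols <- vapply((3 * cod + 1):(3 * cod + 3), function(cp)
      if (cp < ii[1]) cp else cp + (ii[2] - ii[1] + 1), 0)
    within <- which(cpos_cols == s)
    safe <- Filter(function(b) {
      codon <- base$seq[cpos_cols]
      codon[within] <- b
      !paste(codon, collapse = "") %in% STOP_CODONS
    }, cands)
    if (length(safe) == 0) safe <- cands
    sample(safe, 1)
  }, "")

  ids <- c(sprintf("A%02d", seq_len(nA)), sprintf("B%02d", seq_len(nB)))
  mat <- matrix(rep(base$seq, each = nA + nB), nrow = nA + nB,
                dimnames = list(ids, NULL))
  for (k in seq_along(positions))
    mat[hap[, k] == 1, positions[k]] <- alt[k]

  # intronic sequence-type dimorphism at intermediate frequency per locus
  ndiv <- round(type_divergence * length(icols))
  div_sites <- if (ndiv > 0) sort(sample(icols, ndiv)) else integer(0)
  type2_alt <- vapply(div_sites, function(s)
    sample(setdiff(BASES, base$seq[s]), 1), "")
  types <- integer(nA + nB)
  pick2 <- function(n) {
    k <- max(1, min(n - 1, round(n * type_freq)))
    sample(n, k)
  }
  types[seq_len(nA)] <- ifelse(seq_len(nA) %in% pick2(nA), 2L, 1L)
  if (nB > 0)
    types[nA + seq_len(nB)] <- ifelse(seq_len(nB) %in% pick2(nB), 2L, 1L)
  for (k in seq_along(div_sites))
    mat[types == 2L, div_sites[k]] <- type2_alt[k]

  # pseudogene injections: frameshift (1-bp deletion) or premature stop
  pseudo_idx <- if (pseudogene_count > 0)
    sort(sample(nA + nB, pseudogene_count)) else integer(0)
  pseudo_kind <- character(0)
  exon_cols <- setdiff(seq_len(params$L), icols)
  for (i in pseudo_idx) {
    kind <- sample(c("frameshift", "premature stop"), 1)
    if (kind == "frameshift") {
      mat[i, sample(exon_cols[seq_len(ii[1] - 1)], 1)] <- "-"
    } else {
      cod <- sample(seq_len((ii[1] - 1) %/% 3 - 1), 1)  # before the intron
      mat[i, (3 * cod - 2):(3 * cod)] <- c("T", "A", "A")
    }
    pseudo_kind <- c(pseudo_kind, kind)
  }

  aln_A <- alignment(mat[seq_len(nA), , drop = FALSE])
  aln_B <- if (nB > 0) alignment(mat[nA + seq_len(nB), , drop = FALSE])
           else NULL
  truth <- structure(list(
    params = params, seed = seed,
    locus = c(rep("A", nA), rep("B", nB)),
    seq_type = stats::setNames(types, ids),
    pseudogenes = ids[pseudo_idx],
    pseudogene_kind = stats::setNames(pseudo_kind, ids[pseudo_idx]),
    orf_start = base$orf_start, intron_interval = ii,
    div_sites = div_sites, positions = positions,
    causal_sites = NULL), class = "synthetic_truth")
  list(aln_A = aln_A, aln_B = aln_B,
       outgroup = paste(base$seq, collapse = ""), truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d + %d alleles, %d pseudogenes, seed %d\n",
              sum(x$locus == "A"), sum(x$locus == "B"),
              length(x$pseudogenes), x$seed))
  invisible(x)
}

#' Generate phenotype classes from designated causal SNPs
#'
#' Assigns the four functional classes: class I to pseudogene alleles
#' (never flipped); class II to carriers of the derived allele at the
#' designated "insensitivity" site (with probability `penetrance`); the
#' remaining alleles split into III (attenuated HR; carriers of the
#' derived "weak-HR" allele) and IV (strong HR). Labels of non-pseudogene
#' alleles are then flipped independently to a random other class with the
#' given misclassification rate.
#'
#' @param family output of [generate_gene_family()].
#' @param causal_sites optional list `list(insensitivity =, weak_hr =)` of
#'   alignment positions; defaults to the two segregating exonic sites with
#'   minor-allele frequency closest to 0.35 and 0.45.
#' @param penetrance probability a causal carrier shows the causal class.
#' @param misclassification_rate per-allele label-flip probability.
#' @param seed integer seed.
#' @return data.frame with `allele_id` and `phenotype_class`; the chosen
#'   causal sites are attached as attribute `causal_sites` and recorded in
#'   `family$truth` of the returned attribute `truth`.
#' @export
generate_phenotypes <- function(family, causal_sites = NULL, penetrance = 1,
                                misclassification_rate = 0, seed = 1) {
  stopifnot(penetrance >= 0, penetrance <= 1,
            misclassification_rate >= 0, misclassification_rate <= 1)
  set.seed(seed)
  truth <- family$truth
  combined <- rbind(unclass(family$aln_A),
                    if (!is.null(family$aln_B)) unclass(family$aln_B))
  og <- strsplit(family$outgroup, "")[[1]]
  if (is.null(causal_sites)) {
    pos <- truth$positions
    if (length(pos) < 2) stop("too few segregating exonic sites")
    maf <- vapply(pos, function(s) {
      x <- combined[, s]
      x <- x[x != "-"]
      f <- mean(x != og[s])
      min(f, 1 - f)
    }, 0)
    s1 <- pos[which.min(abs(maf - 0.35))]
    s2 <- pos[setdiff(order(abs(maf - 0.45)), which(pos == s1))[1]]
    causal_sites <- list(insensitivity = s1, weak_hr = s2)
  }
  derived_at <- function(site)
    combined[, site] != og[site] & combined[, site] != "-"
  ins <- derived_at(causal_sites$insensitivity)
  weak <- derived_at(causal_sites$weak_hr)
  n <- nrow(combined)
  cls <- ifelse(ins & stats::runif(n) < penetrance, "II",
                ifelse(weak & stats::runif(n) < penetrance, "III", "IV"))
  cls[rownames(combined) %in% truth$pseudogenes] <- "I"
  flip <- cls != "I" & stats::runif(n) < misclassification_rate
  for (i in which(flip))
    cls[i] <- sample(setdiff(c("II", "III", "IV"), cls[i]), 1)
  out <- data.frame(allele_id = rownames(combined), phenotype_class = cls)
  attr(out, "causal_sites") <- causal_sites
  out
}
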
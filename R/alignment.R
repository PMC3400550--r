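#' Alignment container
#'
#' A minimal container for an equal-length nucleotide alignment: a character
#' matrix over {A,C,G,T,-,N} with unique row names (allele identifiers) and
#' 1-based inclusive column coordinates on the alignment. ORF alignments
#' keep their intronic columns, so site numbering runs over exon and intron
#' alike.
#'
#' @param seqs named character vector of equal-length sequences, or a
#'   character matrix of single characters with row names.
#' @return object of class `alignment` (a character matrix).
#' @export
alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop("sequences must carry unique names")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1)
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("alignment must have unique row names")
  if (ncol(mat) < 1 || nrow(mat) < 1) stop("alignment error: empty alignment")
  class(mat) <- c("alignment", class(mat))
  mat
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d sequences x %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

aln_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1, paste, collapse = ""), rownames(aln))
}

#' Read a FASTA multiple-sequence alignment
#'
#' Reads a FASTA file (via Biostrings) and returns an [alignment()]; all
#' records must have equal length. Sequences are upper-cased and record
#' order is preserved.
#'
#' @param path path to a FASTA file.
#' @return an `alignment`.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("format error: no FASTA records in ", path)
  seqs <- stats::setNames(toupper(as.character(set)),
                          sub("\\s.*$", "", names(set)))
  alignment(seqs)
}

#' Write an alignment as FASTA
#'
#' Standard FASTA with 60-column line wrapping. Refuses to write an empty
#' alignment.
#'
#' @param aln an [alignment()].
#' @param path output path.
#' @export
write_fasta <- function(aln, path) {
  if (!inherits(aln, "alignment") || nrow(aln) == 0 || ncol(aln) == 0)
    stop("format error: refusing to write an empty or invalid alignment")
  set <- Biostrings::BStringSet(aln_strings(aln))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

intron_cols <- function(intron_interval, L) {
  if (is.null(intron_interval)) return(integer(0))
  stopifnot(length(intron_interval) == 2)
  if (intron_interval[1] < 1 || intron_interval[2] > L ||
      intron_interval[1] > intron_interval[2])
    stop("coordinate error: intron interval outside alignment")
  seq(intron_interval[1], intron_interval[2])
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Flag pseudogene alleles
#'
#' An allele is flagged as a putative pseudogene when, after removing
#' alignment gaps and the intron, translation from `orf_start` either hits a
#' stop codon before the terminal stop ("premature stop") or the coding
#' length is not a multiple of three ("frameshift"). Codons containing N are
#' skipped (never called as stops).
#'
#' @param aln an [alignment()] of ORF sequences (intron included).
#' @param orf_start 1-based alignment column where the reading frame starts.
#' @param intron_interval integer vector `c(start, end)` of the intron on
#'   alignment coordinates, or NULL if none.
#' @return data.frame with columns `allele`, `pseudogene` (logical),
#'   `reason` ("frameshift", "premature stop" or "").
#' @export
flag_pseudogenes <- function(aln, orf_start, intron_interval = NULL) {
  L <- ncol(aln)
  if (orf_start < 1 || orf_start > L)
    stop("coordinate error: orf_start outside alignment")
  icols <- intron_cols(intron_interval, L)
  keep <- setdiff(seq(orf_start, L), icols)
  res <- lapply(rownames(aln), function(id) {
    chars <- unclass(aln)[id, keep]
    chars <- chars[chars != "-"]
    ncod <- length(chars) %/% 3
    if (length(chars) %% 3 != 0)
      return(data.frame(allele = id, pseudogene = TRUE,
                        reason = "frameshift"))
    codons <- vapply(seq_len(ncod), function(k)
      paste(chars[(3 * k - 2):(3 * k)], collapse = ""), "")
    stops <- which(codons %in% STOP_CODONS)
    premature <- length(stops) > 0 && stops[1] < ncod
    data.frame(allele = id, pseudogene = premature,
               reason = if (premature) "premature stop" else "")
  })
  do.call(rbind, res)
}

#' Assign intronic sequence types by complete-linkage clustering
#'
#' Partitions the alleles into two sequence types by complete-linkage
#' clustering of pairwise nucleotide distance restricted to the intronic
#' columns. Label 1 is the larger group; size ties are broken in favour of
#' the group containing the lexicographically smallest allele id, so the
#' assignment is deterministic. If the intron is monomorphic the result is
#' "untyped" rather than an error.
#'
#' @param aln an [alignment()].
#' @param intron_interval integer `c(start, end)` of the intron.
#' @return a list of class `seqtype_assignment` with elements `labels`
#'   (named integer vector in {1, 2}, or NA when untyped) and `untyped`.
#' @export
assign_sequence_types <- function(aln, intron_interval) {
  if (nrow(aln) < 2) stop("need at least two alleles")
  icols <- intron_cols(intron_interval, ncol(aln))
  if (length(icols) == 0) stop("coordinate error: empty intron interval")
  sub <- unclass(aln)[, icols, drop = FALSE]
  sub[sub %in% c("-", "N")] <- NA
  n <- nrow(sub)
  seg <- apply(sub, 2, function(col) length(unique(stats::na.omit(col))) > 1)
  labels <- stats::setNames(rep(NA_integer_, n), rownames(aln))
  if (!any(seg)) {
    return(structure(list(labels = labels, untyped = TRUE),
                     class = "seqtype_assignment"))
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(sub[i, ]) & !is.na(sub[j, ])
      d[i, j] <- d[j, i] <-
        if (any(ok)) mean(sub[i, ok] != sub[j, ok]) else 0.5
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  grp <- stats::cutree(hc, k = 2)
  ids <- rownames(aln)
  n1 <- sum(grp == 1); n2 <- sum(grp == 2)
  first <- if (n1 != n2) {
    which.max(c(n1, n2))
  } else {
    grp[[which.min(ids)]]  # tie: smallest id's group becomes type 1
  }
  labels[] <- ifelse(grp == first, 1L, 2L)
  structure(list(labels = labels, untyped = FALSE),
            class = "seqtype_assignment")
}

#' @export
print.seqtype_assignment <- function(x, ...) {
  if (x$untyped) cat("sequence types: untyped (intron monomorphic)\n")
  else cat("sequence types:", sum(x$labels == 1), "type-1,",
           sum(x$labels == 2), "type-2 alleles\n")
  invisible(x)
}

#' Extract a biallelic SNP matrix from an alignment
#'
#' Retains only biallelic segregating columns; gaps and N are treated as
#' missing and never called as alleles. Genotypes are coded 0 for the major
#' and 1 for the minor allele (ties broken alphabetically); the minor allele
#' frequency is computed over non-missing alleles.
#'
#' @param aln an [alignment()].
#' @return an object of class `snp_matrix`: list with `positions` (1-based
#'   alignment columns), `geno` (n x S integer matrix, NA = missing), `maf`,
#'   and `minor` / `major` allele characters.
#' @export
snp_table <- function(aln) {
  mat <- unclass(aln)
  mat[mat %in% c("-", "N")] <- NA
  n <- nrow(mat)
  cols <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    tab <- table(col)
    if (length(tab) != 2) return(NULL)
    alleles <- names(sort(tab, decreasing = TRUE))
    if (tab[[alleles[1]]] == tab[[alleles[2]]])
      alleles <- sort(alleles)  # tie: alphabetical major
    g <- ifelse(is.na(col), NA_integer_, as.integer(col == alleles[2]))
    list(pos = j, g = g, maf = sum(g, na.rm = TRUE) / sum(!is.na(g)),
         major = alleles[1], minor = alleles[2])
  })
  cols <- Filter(Negate(is.null), cols)
  if (length(cols) == 0) {
    return(structure(list(positions = integer(0),
                          geno = matrix(NA_integer_, n, 0,
                                        dimnames = list(rownames(aln), NULL)),
                          maf = numeric(0), major = character(0),
                          minor = character(0)),
                     class = "snp_matrix"))
  }
  geno <- do.call(cbind, lapply(cols, `[[`, "g"))
  rownames(geno) <- rownames(aln)
  structure(list(positions = vapply(cols, `[[`, 0L, "pos"),
                 geno = geno,
                 maf = vapply(cols, `[[`, 0, "maf"),
                 major = vapply(cols, `[[`, "", "major"),
                 minor = vapply(cols, `[[`, "", "minor")),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d markers x %d alleles\n",
              length(x$positions), nrow(x$geno)))
  invisible(x)
}

#' Read an allele metadata or phenotype table
#'
#' TSV with a header; expected columns include `allele_id` and any of
#' `species`, `locus`, `seq_type`, `pseudogene`, `phenotype_class`. Alleles
#' assigned to locus C or left unassigned are excluded from
#' population-genetic analyses downstream; this reader only loads the table.
#'
#' @param path path to a tab-separated file.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"allele_id" %in% names(df))
    stop("format error: metadata table needs an allele_id column")
  df
}
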
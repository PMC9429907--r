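# Percent identity between sigma factors on a profile alignment.
#
# Sequences are assumed pre-aligned to a family profile (hmmalign style).
# Identity uses the min-length denominator convention of esl-alipid:
# 100 * identical columns / min(residues_a, residues_b). Optionally the
# alignment is first trimmed to the span of profile reference ("match")
# columns, dropping N- and C-terminal insert states.

#' Read a profile alignment from aligned FASTA
#'
#' Two mask conventions are supported. `mask = "record"` expects a FASTA
#' record (default name `"RF"`) whose sequence marks profile reference columns
#' with `x` and inserts with `.`; that record is removed from the alignment.
#' `mask = "a2m"` derives the mask from case: columns where any sequence has
#' an uppercase residue or `-` are reference columns, lowercase/`.` columns
#' are inserts.
#'
#' @param path Aligned FASTA file.
#' @param mask `"record"` or `"a2m"`.
#' @param mask_record Name of the mask record when `mask = "record"`.
#' @return A `profile_alignment`: list with `sequences` (named character
#'   vector of equal-length aligned strings, gaps `-`) and `reference_mask`
#'   (logical per column).
#' @export
read_profile_alignment <- function(path, mask = c("record", "a2m"),
                                   mask_record = "RF") {
  mask <- match.arg(mask)
  seqs <- Biostrings::readBStringSet(path)
  strs <- as.character(seqs)
  names(strs) <- sub("\\s.*$", "", names(strs))
  if (length(unique(nchar(strs))) != 1)
    stop("read_profile_alignment: sequences have unequal aligned lengths")
  if (mask == "record") {
    if (!mask_record %in% names(strs))
      stop("read_profile_alignment: mask record '", mask_record, "' not found")
    mstr <- strs[[mask_record]]
    strs <- strs[names(strs) != mask_record]
    ref <- strsplit(mstr, "")[[1]] %in% c("x", "X")
  } else {
    mat <- do.call(rbind, strsplit(strs, ""))
    ref <- apply(mat, 2L, function(col) any(col == "-" | grepl("[A-Z]", col)))
    strs <- vapply(strs, function(s) {
      chars <- strsplit(s, "")[[1]]
      chars[chars == "."] <- "-"
      paste(toupper(chars), collapse = "")
    }, "", USE.NAMES = TRUE)
  }
  profile_alignment(strs, ref)
}

#' Construct a profile alignment object
#'
#' @param sequences Named character vector of aligned strings (gap `-`).
#' @param reference_mask Logical vector, one entry per alignment column.
#' @return A `profile_alignment` list.
#' @export
profile_alignment <- function(sequences, reference_mask) {
  len <- unique(nchar(sequences))
  if (length(len) != 1)
    stop("profile_alignment: aligned strings differ in length")
  if (length(reference_mask) != len)
    stop("profile_alignment: mask length != alignment length")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("profile_alignment: sequences must have unique names")
  out <- list(sequences = sequences,
              reference_mask = as.logical(reference_mask))
  class(out) <- "profile_alignment"
  out
}

#' Pairwise percent identity on a profile alignment
#'
#' Identity = 100 x (columns where both sequences carry the same non-gap
#' residue) / min(non-gap length of a, non-gap length of b). With
#' `trim_to_reference = TRUE`, columns strictly before the first and strictly
#' after the last reference-mask column are removed before computing, which
#' drops unaligned N/C-terminal tails hanging off the profile.
#'
#' @param aln A `profile_alignment`.
#' @param name_a,name_b Sequence names present in the alignment.
#' @param trim_to_reference Trim termini beyond profile reference positions.
#' @return Percent identity in \[0, 100\].
#' @export
percent_identity <- function(aln, name_a, name_b, trim_to_reference = TRUE) {
  stopifnot(inherits(aln, "profile_alignment"))
  for (nm in c(name_a, name_b))
    if (!nm %in% names(aln$sequences))
      stop("percent_identity: sequence '", nm, "' not in alignment")
  a <- strsplit(toupper(aln$sequences[[name_a]]), "")[[1]]
  b <- strsplit(toupper(aln$sequences[[name_b]]), "")[[1]]
  keep <- rep(TRUE, length(a))
  if (trim_to_reference) {
    refcols <- which(aln$reference_mask)
    if (length(refcols) == 0)
      stop("percent_identity: no reference columns to trim to")
    keep <- seq_along(a) >= min(refcols) & seq_along(a) <= max(refcols)
  }
  a <- a[keep]; b <- b[keep]
  agap <- a %in% c("-", "."); bgap <- b %in% c("-", ".")
  na <- sum(!agap); nb <- sum(!bgap)
  if (na == 0 || nb == 0)
    stop("percent_identity: sequence all gaps after trimming")
  ident <- sum(!agap & !bgap & a == b)
  100 * ident / min(na, nb)
}

#' Correlation between sequence identity and a phenotype
#'
#' Spearman rank correlation between per-gene percent identity (to a host
#' sigma factor) and a phenotype such as mean spore yield, over the genes
#' shared by both maps.
#'
#' @param identities Named numeric vector, gene -> percent identity.
#' @param phenotype Named numeric vector, gene -> phenotype value.
#' @param exact_n_max Passed to [spearman_correlation()].
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
identity_phenotype_correlation <- function(identities, phenotype,
                                           exact_n_max = 8L) {
  shared <- intersect(names(identities), names(phenotype))
  if (length(shared) < 3)
    stop("identity_phenotype_correlation: fewer than 3 shared genes")
  spearman_correlation(identities[shared], phenotype[shared],
                       exact_n_max = exact_n_max)
}
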
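#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminally to K or R, except when the next
#' residue is P (trypsin specificity), and returns all peptides with up to
#' `missedCleavages` retained internal sites, filtered to a length window.
#' With `missedCleavages = 0` and no length filter the returned peptides
#' concatenate back to the input sequence.
#'
#' @param sequence single amino-acid string (20-letter alphabet, X allowed).
#' @param missedCleavages maximum number of retained internal cleavage sites.
#' @param minLen,maxLen peptide length window (residues).  The defaults
#'   (7-45 with up to 2 missed cleavages) are common shotgun-proteomics
#'   search settings.
#' @return Character vector of peptides ordered by start position, then span.
#' @examples
#' digest("MKRAP", missedCleavages = 0, minLen = 1, maxLen = Inf)
#' @export
digest <- function(sequence, missedCleavages = 2L, minLen = 7L, maxLen = 45L) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  if (minLen > maxLen) stop("'minLen' must be <= 'maxLen'")
  if (missedCleavages < 0L) stop("'missedCleavages' must be non-negative")
  checkAminoAcids(sequence)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n == 0L) return(character())
  ## cleavage after position i: residue i is K/R and i+1 is not P
  sites <- which(res %in% c("K", "R"))
  sites <- sites[sites < n & res[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)
  nfrag <- length(bounds) - 1L
  out <- character()
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + missedCleavages)) {
      pep <- substr(sequence, bounds[i] + 1L, bounds[j + 1L])
      len <- nchar(pep)
      if (len >= minLen && len <= maxLen) out <- c(out, pep)
    }
  }
  out
}

#' Classify peptides by protein-mapping ambiguity
#'
#' Maps each peptide by exact substring search against every protein and
#' assigns the unambiguity class used to restrict protein inference:
#' `1a` (maps to exactly one protein), `3a` (maps to several proteins that
#' all have identical full-length sequences, i.e. one gene-duplicate
#' protein group), or `ambiguous` (shared between non-identical proteins).
#' 3a groups are reported as the sorted id set joined with `";"`.
#'
#' @param peptides character vector of peptide sequences (deduplicated
#'   internally; the output has one row per unique peptide).
#' @param proteome named character vector, [Biostrings::AAStringSet], or a
#'   gene table with `id` and `sequence` columns.  Ids must be unique.
#' @return data.frame with columns `peptide`, `class`, `proteins`
#'   (matching ids, sorted, `";"`-separated) and `n_proteins`.
#' @export
classifyPeptides <- function(peptides, proteome) {
  prot <- asAAStringSet(proteome)
  if (length(prot) == 0L) stop("empty proteome")
  if (anyDuplicated(names(prot))) stop("proteome ids must be unique")
  peptides <- unique(as.character(peptides))
  seqs <- as.character(prot)
  cls <- character(length(peptides))
  hits <- character(length(peptides))
  nh <- integer(length(peptides))
  for (i in seq_along(peptides)) {
    cnt <- Biostrings::vcountPattern(peptides[i], prot, fixed = TRUE)
    ids <- sort(names(prot)[cnt > 0L])
    nh[i] <- length(ids)
    hits[i] <- paste(ids, collapse = ";")
    cls[i] <- if (length(ids) == 1L) "1a"
      else if (length(ids) > 1L && length(unique(seqs[ids])) == 1L) "3a"
      else if (length(ids) > 1L) "ambiguous"
      else "unmapped"
  }
  data.frame(peptide = peptides, class = cls, proteins = hits,
             n_proteins = nh, stringsAsFactors = FALSE)
}

#' Fast peptide class table from tryptic digests
#'
#' Builds the same `peptide`/`class`/`proteins` table as
#' [classifyPeptides()], but only for the tryptic peptides of the given
#' proteome and by exact dictionary lookup instead of substring scanning.
#' A peptide shared by several proteins is `3a` when all carriers have
#' identical full-length sequences and `ambiguous` otherwise.  Unlike the
#' substring scan this does not detect a tryptic peptide of one protein
#' occurring as a non-tryptic substring of another; for synthetic or
#' low-redundancy proteomes the two agree, and the substring scan remains
#' the reference implementation.
#'
#' @param proteome named character vector or [Biostrings::AAStringSet].
#' @param missedCleavages,minLen,maxLen digestion parameters passed to
#'   [digest()].
#' @return data.frame with columns `peptide`, `class`, `proteins`,
#'   `n_proteins`.
#' @export
peptideClassTable <- function(proteome, missedCleavages = 0L,
                              minLen = 7L, maxLen = 45L) {
  prot <- asAAStringSet(proteome)
  if (length(prot) == 0L) stop("empty proteome")
  if (anyDuplicated(names(prot))) stop("proteome ids must be unique")
  seqs <- as.character(prot)
  pools <- lapply(seqs, digest, missedCleavages = missedCleavages,
                  minLen = minLen, maxLen = maxLen)
  long <- data.frame(
    peptide = unlist(pools, use.names = FALSE),
    protein = rep(names(prot), lengths(pools)),
    stringsAsFactors = FALSE)
  long <- unique(long)
  grp <- split(long$protein, long$peptide)
  ids <- vapply(grp, function(g) paste(sort(g), collapse = ";"), character(1))
  nh <- lengths(grp)
  cls <- vapply(names(grp), function(p) {
    g <- grp[[p]]
    if (length(g) == 1L) "1a"
    else if (length(unique(seqs[g])) == 1L) "3a"
    else "ambiguous"
  }, character(1))
  out <- data.frame(peptide = names(grp), class = cls, proteins = ids,
                    n_proteins = as.integer(nh), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a proteome FASTA file
#'
#' @param path FASTA file, one record per protein, id = locus tag.
#' @return Named [Biostrings::AAStringSet].
#' @export
readProteomeFasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a proteome FASTA file
#'
#' @param proteome named character vector or [Biostrings::AAStringSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProteomeFasta <- function(proteome, path) {
  Biostrings::writeXStringSet(asAAStringSet(proteome), path, width = 60L)
  invisible(path)
}

#' Build a reversed decoy proteome
#'
#' Full-protein sequence reversal; decoy ids carry a `rev_` prefix.
#' Reversal preserves length and composition, the standard decoy
#' construction for target-decoy FDR estimation.
#'
#' @param proteome named character vector or [Biostrings::AAStringSet].
#' @return [Biostrings::AAStringSet] of reversed sequences.
#' @export
reverseProteome <- function(proteome) {
  prot <- asAAStringSet(proteome)
  out <- Biostrings::reverse(prot)
  names(out) <- paste0("rev_", names(prot))
  out
}
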
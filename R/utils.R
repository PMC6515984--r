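#' Evaluate an expression with a local, seeded RNG state
#'
#' All generators in the package route their randomness through this helper
#' so that a call is reproducible from its `seed` argument alone and never
#' disturbs the caller's RNG state.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withLocalSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## the 20 standard amino acids
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @noRd
checkAminoAcids <- function(x, allowX = TRUE) {
  alph <- if (allowX) c(AA20, "X") else AA20
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]), alph)
  if (length(bad))
    stop("invalid amino-acid residue(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' @noRd
asAAStringSet <- function(x) {
  if (is(x, "AAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) stop("proteome sequences must be named")
    return(Biostrings::AAStringSet(x))
  }
  if (is.data.frame(x)) {
    if (!all(c("id", "sequence") %in% names(x)))
      stop("gene table must have 'id' and 'sequence' columns")
    return(Biostrings::AAStringSet(setNames(x$sequence, x$id)))
  }
  stop("cannot interpret object of class ", class(x)[1], " as a proteome")
}
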
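DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over the strict A/C/G/T alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' revcomp("GAATTC") # its own reverse complement
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# All k-mers over A<C<G<T in lexicographic order (column order used
# throughout the package).
kmer_names <- function(k) {
  stopifnot(k >= 1)
  grids <- rev(rep(list(DNA_ALPHABET), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

check_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string", call. = FALSE)
  if (grepl("[^ACGT]", seq))
    stop(what, " contains characters outside A/C/G/T", call. = FALSE)
  invisible(seq)
}
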
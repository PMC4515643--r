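#' Normalized k-mer composition of a single sequence
#'
#' Computes the overlapping k-mer composition of a DNA sequence for
#' k = 1..5 (mono- to pentanucleotide composition; feature dimensions
#' 4, 16, 64, 256, 1024). Entry for word `w` is
#' `100 * count(w) / (L - k + 1)` on the percentage basis, so every
#' vector sums to 100 regardless of sequence length.
#'
#' @param seq a DNA string over A/C/G/T, length >= k.
#' @param k word length, 1..5.
#' @param basis `"percent"` (default, sums to 100) or `"fraction"`
#'   (sums to 1).
#' @return named numeric vector of length `4^k` in lexicographic k-mer
#'   order (A < C < G < T).
#' @examples
#' kmer_composition("ACGT", 1)
#' kmer_composition("TCGTCG", 3)[c("TCG", "CGT", "GTC")]
#' @export
kmer_composition <- function(seq, k, basis = c("percent", "fraction")) {
  basis <- match.arg(basis)
  check_dna(seq)
  stopifnot(k >= 1, k <= 5)
  if (nchar(seq) < k)
    stop("sequence of length ", nchar(seq), " is shorter than k = ", k,
         call. = FALSE)
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  v <- counts / (nchar(seq) - k + 1)
  if (basis == "percent") v <- 100 * v
  v
}

#' k-mer feature matrix for an oligonucleotide set
#'
#' Row i is `kmer_composition(set$seq[i], k)`; rows follow set order,
#' columns the fixed lexicographic k-mer order. This is the input
#' representation for the SVM models.
#'
#' @param set an `oligo_set` (all oligos must have length >= k).
#' @param k word length, 1..5.
#' @param basis see [kmer_composition()].
#' @return numeric matrix with `nrow(set)` rows and `4^k` columns;
#'   rownames are oligo ids.
#' @export
featurize_set <- function(set, k, basis = c("percent", "fraction")) {
  basis <- match.arg(basis)
  stopifnot(inherits(set, "oligo_set"), k >= 1, k <= 5)
  short <- which(nchar(set$seq) < k)
  if (length(short))
    stop("oligos shorter than k = ", k, ": ",
         paste(set$id[short], collapse = ", "), call. = FALSE)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(set$seq), width = k)
  v <- counts / (nchar(set$seq) - k + 1)
  if (basis == "percent") v <- 100 * v
  rownames(v) <- set$id
  v
}

#' Write a k-mer feature matrix as TSV
#'
#' @param x matrix from [featurize_set()].
#' @param path output path; k-mer names become column headers, oligo ids
#'   the first column.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(id = rownames(x) %||% seq_len(nrow(x)), x,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
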
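#' Degenerate motif matching
#'
#' A degenerate motif is written as literal nucleotides interleaved with
#' `-` gap markers, e.g. `"TCGTCG-T"`. Literals must match exactly and in
#' order; each gap marker spans between 1 and `gap_max` arbitrary
#' nucleotides (a run of g consecutive markers spans g..g*gap_max).
#' Motifs must start and end with a literal.
#'
#' @param motif motif in text form (literals and `-` gaps).
#' @param seq a DNA string.
#' @param gap_max maximum nucleotides one gap marker may span (>= 1).
#' @return `TRUE` iff the motif occurs anywhere in `seq`.
#' @examples
#' motif_matches("TCGTCG-T", "TCGTCGAT") # TRUE: gap consumes the A
#' motif_matches("TCGTCG-T", "TCGTCGT")  # FALSE: gap must span >= 1 nt
#' @export
motif_matches <- function(motif, seq, gap_max = 1) {
  stopifnot(gap_max >= 1)
  grepl(motif_regex(motif, gap_max), seq, perl = TRUE)
}

# Compile a motif text form into a PCRE pattern. Validates structure.
motif_regex <- function(motif, gap_max = 1) {
  if (length(motif) != 1L || is.na(motif) || !nzchar(motif))
    stop("motif must be a single non-empty string", call. = FALSE)
  if (grepl("[^ACGT-]", motif))
    stop("motif may contain only A/C/G/T and '-': ", motif, call. = FALSE)
  if (grepl("^-|-$", motif))
    stop("malformed motif (leading/trailing gap): ", motif, call. = FALSE)
  # runs of literals and runs of gap markers
  parts <- regmatches(motif, gregexpr("-+|[ACGT]+", motif))[[1]]
  pat <- vapply(parts, function(p) {
    if (startsWith(p, "-")) {
      g <- nchar(p)
      if (gap_max == 1) sprintf(".{%d}", g)
      else sprintf(".{%d,%d}", g, g * gap_max)
    } else p
  }, character(1))
  paste0(pat, collapse = "")
}

# Number of literal (non-gap) characters in a motif.
motif_literal_length <- function(motif) nchar(gsub("-", "", motif))

#' Exclusivity class of a motif
#'
#' Motifs are classed by how many opposing-set sequences they may match:
#' `exclusive` (0), `relaxed_200`, `relaxed_300`, `relaxed_400`
#' (at most 200/300/400). Motifs shared more widely get class `NA`.
#'
#' @param neg_coverage matches in the opposing set (vectorized).
#' @return character vector of class names.
#' @export
motif_class <- function(neg_coverage) {
  cut(neg_coverage, c(-Inf, 0, 200, 300, 400),
      labels = c("exclusive", "relaxed_200", "relaxed_300", "relaxed_400")) |>
    as.character()
}

#' Mine discriminative degenerate motifs
#'
#' Enumerates candidate motifs and ranks those over-represented in the
#' positive set: all literal words of `min_word`..`max_len` nucleotides
#' occurring in the positives, plus single-gap joins of pairs of the
#' `gap_seeds` highest-coverage literal words (total literal length
#' <= `max_len`). Coverage is per sequence: a sequence counts once no
#' matter how many occurrences it contains. Candidates matching more
#' than `max_shared` negative sequences are discarded; survivors are
#' ranked by positive coverage descending, ties broken by shorter text
#' form first, then lexicographically. To mine motifs discriminating
#' the negative class, swap the two set arguments.
#'
#' @param pos,neg `oligo_set`s of positive and negative sequences.
#' @param max_len maximum literal length of a motif (default 10).
#' @param gap_max gap span bound passed to the matcher (default 1).
#' @param n_motifs maximum number of motifs returned (default 100).
#' @param max_shared allowed matches in the opposing set (0 = exclusive;
#'   200/300/400 give the relaxed classes).
#' @param min_word minimum literal word length (default 3).
#' @param gap_seeds number of top literal words used to form gapped
#'   candidates (default 25).
#' @return a `motif_table`: data frame with columns `motif`,
#'   `pos_coverage`, `neg_coverage`, `class`.
#' @export
mine_motifs <- function(pos, neg, max_len = 10, gap_max = 1, n_motifs = 100,
                        max_shared = 0, min_word = 3, gap_seeds = 25) {
  stopifnot(inherits(pos, "oligo_set"), inherits(neg, "oligo_set"),
            n_motifs >= 1, min_word >= 1, max_len >= min_word)
  if (nrow(pos) == 0L || nrow(neg) == 0L)
    stop("both positive and negative sets must be non-empty", call. = FALSE)

  pos_tab <- word_coverage_table(pos$seq, min_word, max_len)
  neg_tab <- word_coverage_table(neg$seq, min_word, max_len)
  words <- names(pos_tab)
  neg_cov <- ifelse(words %in% names(neg_tab), neg_tab[words], 0L)
  cand <- data.frame(motif = words,
                     pos_coverage = as.integer(pos_tab),
                     neg_coverage = as.integer(neg_cov),
                     stringsAsFactors = FALSE)

  # gapped candidates: top literal words joined by one gap
  seeds <- cand$motif[order(-cand$pos_coverage, nchar(cand$motif), cand$motif)]
  seeds <- head(seeds, gap_seeds)
  if (length(seeds) >= 1) {
    pairs <- expand.grid(a = seeds, b = seeds, stringsAsFactors = FALSE)
    pairs <- pairs[nchar(pairs$a) + nchar(pairs$b) <= max_len, , drop = FALSE]
    if (nrow(pairs)) {
      gm <- paste0(pairs$a, "-", pairs$b)
      gm <- unique(gm)
      pc <- vapply(gm, function(m)
        sum(motif_matches(m, pos$seq, gap_max)), integer(1))
      nc <- vapply(gm, function(m)
        sum(motif_matches(m, neg$seq, gap_max)), integer(1))
      keep <- pc > 0L
      cand <- rbind(cand, data.frame(motif = gm[keep],
                                     pos_coverage = pc[keep],
                                     neg_coverage = nc[keep],
                                     stringsAsFactors = FALSE))
    }
  }

  cand <- cand[cand$neg_coverage <= max_shared, , drop = FALSE]
  cand <- cand[order(-cand$pos_coverage, nchar(cand$motif), cand$motif), ,
               drop = FALSE]
  cand <- head(cand, n_motifs)
  cand$class <- motif_class(cand$neg_coverage)
  rownames(cand) <- NULL
  class(cand) <- c("motif_table", "data.frame")
  cand
}

# Per-sequence coverage counts of every literal subword of the given
# length range: table mapping word -> number of sequences containing it.
word_coverage_table <- function(seqs, min_word, max_len) {
  per_seq <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < min_word) return(character())
    words <- unlist(lapply(min_word:min(max_len, L), function(w)
      substring(s, 1:(L - w + 1), w:L)))
    unique(words)
  })
  tab <- table(unlist(per_seq))
  stats::setNames(as.integer(tab), names(tab))
}

#' Top-n motifs by positive coverage
#'
#' Returns the first `n` motifs under the mining order (coverage
#' descending, then shorter text form, then lexicographic); fewer if the
#' table is shorter. Used to form the Top10/Top20 motif lists of the
#' hybrid models.
#'
#' @param motifs a `motif_table` from [mine_motifs()].
#' @param n how many motifs to keep.
#' @return a `motif_table` of at most `n` rows.
#' @export
top_n_by_coverage <- function(motifs, n) {
  stopifnot(n >= 1)
  ord <- order(-motifs$pos_coverage, nchar(motifs$motif), motifs$motif)
  out <- head(motifs[ord, , drop = FALSE], n)
  rownames(out) <- NULL
  class(out) <- c("motif_table", "data.frame")
  out
}

#' Write/read a motif table as TSV
#'
#' Columns: motif (text form, `-` = gap), pos_coverage, neg_coverage,
#' class.
#'
#' @param motifs a `motif_table`.
#' @param path file path.
#' @return `path` (write) or a `motif_table` (read).
#' @export
write_motifs <- function(motifs, path) {
  write.table(as.data.frame(motifs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_motifs
#' @export
read_motifs <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  class(x) <- c("motif_table", "data.frame")
  x
}
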
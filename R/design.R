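#' Fixed-length window scan of a query sequence
#'
#' Slides a window of fixed length over the query at step 1 and scores
#' every window with a trained model (hybrid score when motifs are
#' attached), mapping the immunomodulatory regions of a longer DNA
#' sequence. Coordinates are 1-based inclusive.
#'
#' @param model an `imodn_model`, or any function mapping a character
#'   vector of sequences to numeric scores.
#' @param seq query DNA string.
#' @param window window length (<= `nchar(seq)`; for the bundled models
#'   5..35).
#' @param threshold decision threshold for the IMODN call (defaults to
#'   the model's recorded threshold, or 0 for a function scorer).
#' @return data frame of `ScanHit`s: start, end, window_seq, score,
#'   call.
#' @export
window_scan <- function(model, seq, window, threshold = NULL) {
  check_dna(seq)
  L <- nchar(seq)
  if (window > L) stop("window longer than the sequence", call. = FALSE)
  stopifnot(window >= 1)
  starts <- seq_len(L - window + 1)
  wins <- substring(seq, starts, starts + window - 1)
  scored <- score_with(model, wins)
  thr <- threshold %||% scored$threshold
  data.frame(start = starts, end = starts + window - 1, window_seq = wins,
             score = unname(scored$score),
             call = ifelse(scored$score >= thr, "IMODN", "non-IMODN"),
             stringsAsFactors = FALSE)
}

# Score sequences with either an imodn_model (hybrid when motifs are
# attached) or a plain scoring function.
score_with <- function(model, seqs) {
  if (inherits(model, "imodn_model"))
    list(score = predict(model, seqs, type = "hybrid"),
         threshold = model$threshold)
  else if (is.function(model))
    list(score = model(seqs), threshold = 0)
  else stop("model must be an imodn_model or a scoring function",
            call. = FALSE)
}

#' All single-substitution analogs of an oligonucleotide
#'
#' Generates the complete Hamming-distance-1 neighbourhood: exactly
#' `3 * nchar(seq)` analogs, ordered by position then alphabetic
#' substitute; ids encode the change (e.g. `"5C>T"`).
#'
#' @param seq parent DNA string.
#' @return an `oligo_set` of analogs.
#' @export
generate_analogs <- function(seq) {
  check_dna(seq)
  L <- nchar(seq)
  ids <- character(0); seqs <- character(0)
  for (i in seq_len(L)) {
    from <- substr(seq, i, i)
    for (nt in setdiff(DNA_ALPHABET, from)) {
      cand <- seq
      substr(cand, i, i) <- nt
      ids <- c(ids, paste0(i, from, ">", nt))
      seqs <- c(seqs, cand)
    }
  }
  oligo_set(seqs, ids, name = paste0("analogs_of_", seq))
}

#' Virtual screening of single-substitution analogs
#'
#' Scores the parent oligonucleotide and all `3L` analogs with a model
#' and ranks the analogs by score (descending; ties keep the
#' position/alphabet generation order), reporting the score change
#' versus the parent. The parent is always the first row.
#'
#' @param model an `imodn_model` or scoring function (see
#'   [window_scan()]).
#' @param seq parent DNA string.
#' @return data frame: id, seq, score, delta (score - parent score).
#' @export
virtual_screen <- function(model, seq) {
  analogs <- generate_analogs(seq)
  sc <- score_with(model, c(seq, analogs$seq))$score
  parent <- data.frame(id = "parent", seq = seq, score = sc[1], delta = 0,
                       stringsAsFactors = FALSE)
  tab <- data.frame(id = analogs$id, seq = analogs$seq, score = sc[-1],
                    delta = sc[-1] - sc[1], stringsAsFactors = FALSE)
  tab <- tab[order(-tab$score, seq_len(nrow(tab))), , drop = FALSE]
  out <- rbind(parent, tab)
  rownames(out) <- NULL
  out
}

#' Find reverse-complement palindromes
#'
#' Reports all maximal even-length substrings that equal their own
#' reverse complement (the DNA-biology sense of palindrome, e.g. the
#' EcoRI site GAATTC) of at least `min_len` nucleotides. Each palindrome
#' center yields at most one maximal hit. With `strict = TRUE` only a
#' wholly palindromic input is reported.
#'
#' @param seq DNA string.
#' @param min_len minimum palindrome length (even, >= 4; default 6).
#' @param strict if `TRUE`, test the whole sequence only.
#' @return data frame of `PalindromeHit`s: start (1-based), length,
#'   subseq.
#' @export
find_palindromes <- function(seq, min_len = 6, strict = FALSE) {
  check_dna(seq)
  stopifnot(min_len >= 4, min_len %% 2 == 0)
  L <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (strict) {
    hit <- L %% 2 == 0 && L >= min_len && seq == revcomp(seq)
    return(if (hit)
      data.frame(start = 1L, length = L, subseq = seq,
                 stringsAsFactors = FALSE)
      else empty_palindromes())
  }
  out <- empty_palindromes()
  for (c0 in seq_len(max(L - 1, 0))) {
    l <- 0
    while (c0 - l >= 1 && c0 + 1 + l <= L &&
           ch[c0 - l] == comp[[ch[c0 + 1 + l]]]) l <- l + 1
    if (2 * l >= min_len) {
      st <- c0 - l + 1
      out <- rbind(out, data.frame(start = st, length = 2L * l,
                                   subseq = substr(seq, st, c0 + l),
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_palindromes <- function() {
  data.frame(start = integer(), length = integer(), subseq = character(),
             stringsAsFactors = FALSE)
}

#' Load a restriction enzyme table
#'
#' TSV with columns name, site, offset (cut position within the
#' recognition site, 0..nchar(site)). A small built-in table (EcoRI,
#' BamHI, HindIII, DpnII, AluI) ships with the package and is used when
#' `path` is omitted.
#'
#' @param path TSV path; default the built-in table.
#' @return data frame (name, site, offset).
#' @export
load_enzymes <- function(path = system.file("extdata",
                                            "restriction_enzymes.tsv",
                                            package = "imodn")) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Virtual restriction digest
#'
#' Locates every forward-strand occurrence of each recognition site and
#' cuts at `site_start + offset - 1` / `site_start + offset` (offset 0
#' cuts before the site). Fragments concatenate exactly to the input;
#' the cutting enzymes are reported at each fragment boundary.
#' Fragments of model length (5-35 nt) can be piped to
#' [predict.imodn_model()] to flag immunomodulatory products.
#'
#' @param seq DNA string to digest.
#' @param enzymes data frame (name, site, offset), e.g. from
#'   [load_enzymes()].
#' @return data frame of `DigestFragment`s: start, end (1-based
#'   inclusive), seq, left_enzyme, right_enzyme (empty at the input
#'   ends).
#' @export
digest <- function(seq, enzymes = load_enzymes()) {
  check_dna(seq)
  req <- c("name", "site", "offset")
  if (!all(req %in% names(enzymes)))
    stop("enzymes must have columns name, site, offset", call. = FALSE)
  if (nrow(enzymes) == 0) stop("empty enzyme table", call. = FALSE)
  ok <- !grepl("[^ACGT]", enzymes$site) & nzchar(enzymes$site) &
    enzymes$offset >= 0 & enzymes$offset <= nchar(enzymes$site)
  if (any(!ok))
    stop("invalid enzyme spec: ",
         paste(enzymes$name[!ok], collapse = ", "), call. = FALSE)
  L <- nchar(seq)
  cuts <- data.frame(pos = integer(), enzyme = character())
  for (j in seq_len(nrow(enzymes))) {
    starts <- Biostrings::start(Biostrings::matchPattern(enzymes$site[j], seq))
    pos <- starts - 1L + enzymes$offset[j]  # cut after this many nt
    pos <- pos[pos > 0 & pos < L]
    if (length(pos))
      cuts <- rbind(cuts, data.frame(pos = pos, enzyme = enzymes$name[j]))
  }
  cutpos <- sort(unique(cuts$pos))
  bounds <- c(0L, cutpos, L)
  frag_start <- bounds[-length(bounds)] + 1L
  frag_end <- bounds[-1]
  enz_at <- function(p) {
    if (length(p) == 0 || !p %in% cuts$pos) return("")
    paste(sort(unique(cuts$enzyme[cuts$pos == p])), collapse = ",")
  }
  data.frame(start = frag_start, end = frag_end,
             seq = substring(seq, frag_start, frag_end),
             left_enzyme = vapply(frag_start - 1L, enz_at, ""),
             right_enzyme = vapply(frag_end, enz_at, ""),
             stringsAsFactors = FALSE)
}

#' Map known oligonucleotides onto a sequence
#'
#' Finds every exact occurrence of each library oligo in the query, on
#' the forward and reverse-complement strands (exact-substring search;
#' a hook for an external aligner can be layered on top for inexact
#' matching).
#'
#' @param seq query DNA string.
#' @param library an `oligo_set` of known oligos (non-empty).
#' @return data frame: id, start (1-based on the forward strand),
#'   strand (`"+"`/`"-"`).
#' @export
map_known <- function(seq, library) {
  check_dna(seq)
  stopifnot(inherits(library, "oligo_set"))
  if (nrow(library) == 0) stop("empty library", call. = FALSE)
  res <- lapply(seq_len(nrow(library)), function(i) {
    oligo <- library$seq[i]
    if (nchar(oligo) > nchar(seq)) return(NULL)
    fwd <- Biostrings::start(Biostrings::matchPattern(oligo, seq))
    # palindromic oligos legitimately hit both strands at the same start
    rev <- Biostrings::start(Biostrings::matchPattern(revcomp(oligo), seq))
    rbind(
      if (length(fwd)) data.frame(id = library$id[i], start = fwd,
                                  strand = "+", stringsAsFactors = FALSE),
      if (length(rev)) data.frame(id = library$id[i], start = rev,
                                  strand = "-", stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(id = character(), start = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  out <- out[order(out$id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
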
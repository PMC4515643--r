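#' Build a position-specific quantitative matrix
#'
#' A quantitative matrix (QM) contrasts per-position word frequencies
#' between a positive and a negative set. Entry (w, i) is
#' `f_pos(i, w) - f_neg(i, w)` where `f(i, w)` is the smoothed fraction
#' of sequences long enough to have position i whose word at position i
#' (1-based) is w: `(count + pseudocount) / (n_i + 4^k * pseudocount)`.
#' The mononucleotide QM is 4 x `max_len`, the dinucleotide QM
#' 16 x (`max_len` - 1). The frequency difference is bounded in
#' \[-1, 1\], defined when a frequency is 0, and exactly antisymmetric
#' under swapping the two sets; a log-odds variant is available.
#'
#' @param pos,neg non-empty `oligo_set`s, all oligos of length
#'   <= `max_len`.
#' @param k word length, 1 (mononucleotide) or 2 (dinucleotide).
#' @param max_len maximum oligo length (default 35).
#' @param pseudocount smoothing count added per word (default 0.5).
#' @param type `"diff"` (default) or `"logodds"`.
#' @return a `quant_matrix`: list with `entries` (4^k x positions
#'   matrix), `k`, `max_len`, `pseudocount`, `type`.
#' @export
build_qm <- function(pos, neg, k = 1, max_len = 35, pseudocount = 0.5,
                     type = c("diff", "logodds")) {
  type <- match.arg(type)
  if (!k %in% c(1, 2)) stop("k must be 1 or 2", call. = FALSE)
  stopifnot(inherits(pos, "oligo_set"), inherits(neg, "oligo_set"),
            nrow(pos) > 0, nrow(neg) > 0, pseudocount > 0)
  too_long <- c(pos$seq, neg$seq)[nchar(c(pos$seq, neg$seq)) > max_len]
  if (length(too_long))
    stop("oligos longer than max_len = ", max_len, call. = FALSE)
  fp <- position_freqs(pos$seq, k, max_len, pseudocount)
  fn <- position_freqs(neg$seq, k, max_len, pseudocount)
  entries <- switch(type, diff = fp - fn, logodds = log(fp / fn))
  structure(list(k = k, max_len = max_len, entries = entries,
                 pseudocount = pseudocount, type = type),
            class = "quant_matrix")
}

# Smoothed per-position word frequencies: 4^k x (max_len - k + 1).
# f(i, w) counts only sequences long enough to contain position i.
position_freqs <- function(seqs, k, max_len, pseudocount) {
  words <- kmer_names(k)
  P <- max_len - k + 1
  f <- matrix(0, length(words), P, dimnames = list(words, seq_len(P)))
  lens <- nchar(seqs)
  for (i in seq_len(P)) {
    long_enough <- lens >= i + k - 1
    n_i <- sum(long_enough)
    w_i <- substr(seqs[long_enough], i, i + k - 1)
    counts <- table(factor(w_i, levels = words))
    f[, i] <- (as.numeric(counts) + pseudocount) /
      (n_i + length(words) * pseudocount)
  }
  f
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("<quant_matrix> k=%d (%s), %d x %d, pseudocount=%g\n",
              x$k, x$type, nrow(x$entries), ncol(x$entries), x$pseudocount))
  invisible(x)
}

#' Score a sequence with a quantitative matrix
#'
#' The QM score is the mean of the matrix entries over the positions the
#' sequence occupies (positions 1..L-k+1), so scores of 5-mers and
#' 35-mers share one scale.
#'
#' @param qm a `quant_matrix`.
#' @param seq DNA string with `k <= nchar(seq) <= max_len`.
#' @return numeric score.
#' @export
qm_score <- function(qm, seq) {
  stopifnot(inherits(qm, "quant_matrix"))
  check_dna(seq)
  L <- nchar(seq)
  if (L > qm$max_len)
    stop("sequence longer than the matrix (", qm$max_len, " nt)",
         call. = FALSE)
  if (L < qm$k) stop("sequence shorter than k = ", qm$k, call. = FALSE)
  idx <- seq_len(L - qm$k + 1)
  words <- substring(seq, idx, idx + qm$k - 1)
  mean(qm$entries[cbind(words, idx)])
}

#' Minimal-mutation redesign against a quantitative matrix
#'
#' Greedy plan moving a sequence's QM score towards a target: at each
#' step the single substitution moving the score furthest in the target
#' direction is applied (ties: leftmost position, then alphabetic
#' substitute). The direction is implied by the sign of
#' `target - qm_score(seq)`, so the same routine turns predicted
#' non-IMODNs into IMODNs and vice versa. For the mononucleotide QM,
#' position contributions are independent, so the greedy plan is
#' globally minimal. An unmet target is reported, not raised.
#'
#' @param qm a `quant_matrix`.
#' @param seq DNA string to redesign.
#' @param target target score.
#' @param direction `"up"` (default; raise the score to at least
#'   `target`, empty plan if already there), `"down"` (lower it to at
#'   most `target`), or `"auto"` (direction from the sign of
#'   `target - qm_score(seq)`).
#' @param max_steps cap on the number of substitutions (default: the
#'   sequence length).
#' @return a `mutation_plan`: list with `plan` (data frame of position,
#'   from, to, score_after), `start_score`, `target`, `achieved`,
#'   `final_seq`.
#' @export
qm_min_mutations <- function(qm, seq, target,
                             direction = c("up", "down", "auto"),
                             max_steps = nchar(seq)) {
  direction <- match.arg(direction)
  stopifnot(inherits(qm, "quant_matrix"))
  check_dna(seq)
  cur <- seq
  s0 <- qm_score(qm, cur)
  up <- switch(direction, up = TRUE, down = FALSE, auto = target >= s0)
  reached <- function(s) if (up) s >= target else s <= target
  plan <- data.frame(position = integer(), from = character(),
                     to = character(), score_after = numeric(),
                     stringsAsFactors = FALSE)
  s_cur <- s0
  while (!reached(s_cur) && nrow(plan) < max_steps) {
    best <- NULL
    for (i in seq_len(nchar(cur))) {
      from <- substr(cur, i, i)
      for (nt in setdiff(DNA_ALPHABET, from)) {
        cand <- cur
        substr(cand, i, i) <- nt
        s <- qm_score(qm, cand)
        gain <- if (up) s - s_cur else s_cur - s
        if (gain > 0 && (is.null(best) || gain > best$gain + 1e-12)) {
          best <- list(i = i, from = from, to = nt, seq = cand, s = s,
                       gain = gain)
        }
      }
    }
    if (is.null(best)) break  # no substitution improves the score
    cur <- best$seq
    s_cur <- best$s
    plan <- rbind(plan, data.frame(position = best$i, from = best$from,
                                   to = best$to, score_after = best$s,
                                   stringsAsFactors = FALSE))
  }
  structure(list(plan = plan, start_score = s0, target = target,
                 achieved = reached(s_cur), final_seq = cur),
            class = "mutation_plan")
}

#' @export
print.mutation_plan <- function(x, ...) {
  cat(sprintf("<mutation_plan> %d mutation(s), score %.4f -> %.4f (target %.4f, %s)\n",
              nrow(x$plan), x$start_score,
              if (nrow(x$plan)) x$plan$score_after[nrow(x$plan)] else x$start_score,
              x$target, if (x$achieved) "met" else "NOT met"))
  if (nrow(x$plan)) print.data.frame(x$plan)
  invisible(x)
}

#' Write/read a quantitative matrix as TSV
#'
#' Rows are words in lexicographic order, columns positions
#' 1..`max_len - k + 1`; the mononucleotide matrix is 4 x 35 and the
#' dinucleotide matrix 16 x 34 at `max_len = 35`.
#'
#' @param qm a `quant_matrix`.
#' @param path file path.
#' @return `path` (write) or a `quant_matrix` (read).
#' @export
write_qm <- function(qm, path) {
  df <- data.frame(word = rownames(qm$entries), qm$entries,
                   check.names = FALSE)
  colnames(df)[-1] <- paste0("pos", seq_len(ncol(qm$entries)))
  hdr <- sprintf("# quant_matrix k=%d max_len=%d pseudocount=%g type=%s",
                 qm$k, qm$max_len, qm$pseudocount, qm$type)
  writeLines(hdr, path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_qm
#' @export
read_qm <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- read.delim(path, skip = 1, check.names = FALSE,
                   stringsAsFactors = FALSE)
  entries <- as.matrix(df[, -1, drop = FALSE])
  rownames(entries) <- df$word
  colnames(entries) <- seq_len(ncol(entries))
  structure(list(k = as.integer(vals[["k"]]),
                 max_len = as.integer(vals[["max_len"]]),
                 entries = entries,
                 pseudocount = as.numeric(vals[["pseudocount"]]),
                 type = vals[["type"]]),
            class = "quant_matrix")
}
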
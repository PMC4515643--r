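# Independent brute-force oracles used to verify the package's
# implementations. These deliberately avoid the code paths they check.

rand_dna <- function(len, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
        collapse = "")
}

# naive sliding-window k-mer counter
oracle_kmer_counts <- function(seq, k) {
  L <- nchar(seq)
  words <- substring(seq, 1:(L - k + 1), k:L)
  counts <- table(factor(words, levels = imodn:::kmer_names(k)))
  as.numeric(counts)
}

# all-pairs Mann-Whitney AUC
oracle_auc <- function(scores, y) {
  sp <- scores[y]; sn <- scores[!y]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# direct-formula confusion metrics
oracle_metrics <- function(tp, fp, tn, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  c(sen = 100 * tp / (tp + fn),
    spec = 100 * tn / (tn + fp),
    acc = 100 * (tp + tn) / (tp + fp + tn + fn),
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den))
}

# motif matching by explicit enumeration of all gap-length expansions:
# every gap marker is replaced by each possible number of wildcard
# positions and the resulting fixed-width patterns are tried at every
# offset.
oracle_motif_match <- function(motif, seq, gap_max) {
  parts <- regmatches(motif, gregexpr("-+|[ACGT]+", motif))[[1]]
  gaps <- which(startsWith(parts, "-"))
  spans <- lapply(gaps, function(g) {
    n <- nchar(parts[g]); seq(n, n * gap_max)
  })
  combos <- if (length(spans)) expand.grid(spans) else data.frame(row.names = 1)
  for (r in seq_len(nrow(combos))) {
    pieces <- parts
    for (j in seq_along(gaps))
      pieces[gaps[j]] <- strrep(".", combos[r, j])
    pat <- paste(pieces, collapse = "")
    w <- nchar(pat)
    L <- nchar(seq)
    if (w > L) next
    for (off in 1:(L - w + 1)) {
      window <- substr(seq, off, off + w - 1)
      if (all(mapply(function(a, b) a == "." || a == b,
                     strsplit(pat, "")[[1]], strsplit(window, "")[[1]])))
        return(TRUE)
    }
  }
  FALSE
}

# all even substrings equal to their own reverse complement, filtered
# to the maximal one per center
oracle_palindromes <- function(seq, min_len) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  L <- nchar(seq)
  hits <- list()
  if (L < 2) return(data.frame(start = integer(), length = integer(),
                               subseq = character(), stringsAsFactors = FALSE))
  for (st in 1:(L - 1)) for (en in (st + 1):L) {
    w <- en - st + 1
    if (w %% 2 != 0) next
    sub <- substr(seq, st, en)
    if (sub == rc(sub)) {
      center <- st + w / 2 - 1  # position left of the center gap
      key <- as.character(center)
      if (is.null(hits[[key]]) || w > hits[[key]]$length)
        hits[[key]] <- list(start = st, length = w, subseq = sub)
    }
  }
  hits <- hits[vapply(hits, function(h) h$length >= min_len, logical(1))]
  if (!length(hits))
    return(data.frame(start = integer(), length = integer(),
                      subseq = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(hits, as.data.frame))
  df <- df[order(df$start, df$length), ]
  rownames(df) <- NULL
  df
}

# union of cut positions by scanning every offset for every site
oracle_cut_positions <- function(seq, enzymes) {
  L <- nchar(seq)
  cuts <- integer()
  for (j in seq_len(nrow(enzymes))) {
    site <- enzymes$site[j]; w <- nchar(site)
    for (st in seq_len(L - w + 1))
      if (substr(seq, st, st + w - 1) == site)
        cuts <- c(cuts, st - 1 + enzymes$offset[j])
  }
  sort(unique(cuts[cuts > 0 & cuts < L]))
}

# per-position word frequency recount (unsmoothed counts; the test adds
# the smoothing arithmetic itself)
oracle_position_count <- function(seqs, word, i) {
  k <- nchar(word)
  eligible <- nchar(seqs) >= i + k - 1
  list(count = sum(substr(seqs[eligible], i, i + k - 1) == word),
       n = sum(eligible))
}

# tiny labelled set builder
toy_set <- function(seqs, label = "unknown", ids = NULL) {
  oligo_set(seqs, id = ids, label = label)
}
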
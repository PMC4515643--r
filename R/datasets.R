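#' Parameters of the synthetic benchmark generator
#'
#' The generator emulates the structure of curated immunomodulatory ODN
#' collections: positives are short (5-35 nt) T-rich oligos (~30% T)
#' carrying the canonical stimulatory motif TCGTCG in a fraction of
#' sequences, negatives are CpG-island-like fragments (C-rich, T-poor,
#' CpG-enriched). Defaults are fixed once and define the benchmark's
#' study conditions.
#'
#' @param n_pos,n_neg numbers of positive/negative oligos.
#' @param length_range inclusive length bounds (default 5-35 nt).
#' @param pos_mono positive mononucleotide probabilities
#'   (A/C/G/T; default .22/.25/.23/.30).
#' @param neg_mono negative base probabilities (default .25/.34/.25/.16).
#' @param planted_motif literal motif inserted into positives
#'   (default `"TCGTCG"`).
#' @param plant_rate fraction of positives carrying the motif
#'   (default 0.6).
#' @param neg_cpg_boost multiplicative CpG (C to G transition)
#'   enrichment of the negative first-order chain (default 4).
#' @param seed integer seed.
#' @return a `synth_params` list.
#' @export
synth_params <- function(n_pos = 400, n_neg = 400, length_range = c(5, 35),
                         pos_mono = c(A = .22, C = .25, G = .23, T = .30),
                         neg_mono = c(A = .25, C = .34, G = .25, T = .16),
                         planted_motif = "TCGTCG", plant_rate = 0.6,
                         neg_cpg_boost = 4, seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1,
            length(length_range) == 2, length_range[1] >= 1,
            length_range[2] >= length_range[1],
            abs(sum(pos_mono) - 1) < 1e-8, abs(sum(neg_mono) - 1) < 1e-8,
            all(pos_mono >= 0), all(neg_mono >= 0),
            plant_rate >= 0, plant_rate <= 1, neg_cpg_boost > 0)
  check_dna(planted_motif, "planted_motif")
  if (nchar(planted_motif) > length_range[2])
    stop("planted motif longer than the maximum length", call. = FALSE)
  structure(list(n_pos = n_pos, n_neg = n_neg, length_range = length_range,
                 pos_mono = pos_mono, neg_mono = neg_mono,
                 planted_motif = planted_motif, plant_rate = plant_rate,
                 neg_cpg_boost = neg_cpg_boost, seed = seed),
            class = "synth_params")
}

#' CpG-boosted first-order transition matrix
#'
#' Each row is the base composition with the C-row's C->G transition
#' multiplied by `boost` and renormalized — a minimal first-order chain
#' mimicking the CpG excess of island fragments. The boost shifts the
#' chain's stationary marginal slightly away from `mono` (documented in
#' the methods vignette); [chain_stationary()] returns the realized
#' marginal.
#'
#' @param mono base probabilities (named A/C/G/T).
#' @param boost C->G multiplicative factor.
#' @return 4 x 4 row-stochastic matrix.
#' @export
cpg_chain_matrix <- function(mono, boost) {
  P <- matrix(rep(mono, each = 4), 4, 4,
              dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  P["C", "G"] <- P["C", "G"] * boost
  P["C", ] <- P["C", ] / sum(P["C", ])
  P
}

#' Stationary distribution of a transition matrix
#'
#' @param P row-stochastic matrix.
#' @return named probability vector.
#' @export
chain_stationary <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  stats::setNames(v / sum(v), rownames(P))
}

# Vectorized i.i.d. sequence generation from mono-nucleotide probs.
sample_iid_seqs <- function(lens, mono) {
  total <- sum(lens)
  nts <- sample(DNA_ALPHABET, total, replace = TRUE, prob = mono)
  vapply(split(nts, rep(seq_along(lens), lens)),
         paste, character(1), collapse = "")
}

# Vectorized first-order chain generation: one column of nucleotides
# per step, sampled per previous-state group.
sample_chain_seqs <- function(lens, mono, P) {
  n <- length(lens)
  maxL <- max(lens)
  m <- matrix(NA_character_, n, maxL)
  m[, 1] <- sample(DNA_ALPHABET, n, replace = TRUE, prob = mono)
  for (i in seq_len(maxL - 1)) {
    alive <- which(lens > i)
    if (!length(alive)) break
    prev <- m[alive, i]
    for (nt in DNA_ALPHABET) {
      ix <- alive[prev == nt]
      if (length(ix))
        m[ix, i + 1] <- sample(DNA_ALPHABET, length(ix), replace = TRUE,
                               prob = P[nt, ])
    }
  }
  vapply(seq_len(n), function(j)
    paste(m[j, seq_len(lens[j])], collapse = ""), character(1))
}

#' Generate the synthetic benchmark
#'
#' Draws positives nucleotide-wise from `pos_mono` with the planted
#' motif inserted at a uniform position in a `plant_rate` fraction of
#' them (planted sequences are drawn long enough to hold the motif);
#' negatives come from the CpG-boosted first-order chain. Lengths are
#' uniform over `length_range`. The labelled sets are split 80/20 per
#' class into a [dataset_bundle]. Fully deterministic given the seed.
#'
#' @param params a [synth_params()] object (or arguments passed on to
#'   it via `...`).
#' @param train_frac training fraction of the split.
#' @param ... used to build `params` when it is missing.
#' @return a `dataset_bundle` (see [train_valid_split()]).
#' @export
synth_benchmark <- function(params = synth_params(...), train_frac = 0.8,
                            ...) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  mlen <- nchar(p$planted_motif)
  pos_seqs <- with_seed(p$seed, {
    lens <- sample(p$length_range[1]:p$length_range[2], p$n_pos,
                   replace = TRUE)
    plant <- runif(p$n_pos) < p$plant_rate
    # planted sequences must hold the motif
    lo <- max(p$length_range[1], mlen)
    short <- plant & lens < lo
    if (any(short))
      lens[short] <- sample(lo:p$length_range[2], sum(short), replace = TRUE)
    seqs <- sample_iid_seqs(lens, p$pos_mono)
    for (i in which(plant)) {
      st <- sample.int(lens[i] - mlen + 1, 1)
      substr(seqs[i], st, st + mlen - 1) <- p$planted_motif
    }
    seqs
  })
  neg_seqs <- with_seed(p$seed + 1L, {
    lens <- sample(p$length_range[1]:p$length_range[2], p$n_neg,
                   replace = TRUE)
    P <- cpg_chain_matrix(p$neg_mono, p$neg_cpg_boost)
    sample_chain_seqs(lens, p$neg_mono, P)
  })
  pos <- oligo_set(pos_seqs, paste0("pos_", seq_along(pos_seqs)),
                   label = "positive", name = "synthetic_positives")
  neg <- oligo_set(neg_seqs, paste0("neg_", seq_along(neg_seqs)),
                   label = "negative", name = "synthetic_negatives")
  train_valid_split(pos, neg, train_frac = train_frac, seed = p$seed + 2L)
}

#' Fragment CpG islands into negative oligonucleotides
#'
#' Draws `n` random fragments from the islands of a genome: an island
#' is picked uniformly among the usable ones, the fragment length
#' uniformly over `length_range` (capped by the island width) and the
#' start uniformly within the island. Fragments are labelled negative.
#' Islands shorter than the minimum length are skipped with a warning.
#'
#' @param genome path to a genome FASTA.
#' @param islands path to a CpG-island BED file (0-based half-open).
#' @param n number of fragments.
#' @param length_range inclusive fragment length bounds (default 5-35).
#' @param seed integer seed.
#' @return an `oligo_set` of `n` negative fragments.
#' @export
fragment_cpg_islands <- function(genome, islands, n, length_range = c(5, 35),
                                 seed = 1) {
  stopifnot(n >= 1, length_range[1] >= 1,
            length_range[2] >= length_range[1])
  contigs <- Biostrings::readDNAStringSet(genome)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gr <- rtracklayer::import(islands, format = "BED")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)   # 1-based inclusive after import
  ends <- GenomicRanges::end(gr)
  if (!all(chrom %in% names(contigs)))
    stop("BED interval on a contig absent from the genome", call. = FALSE)
  if (any(ends > Biostrings::width(contigs[chrom])))
    stop("BED interval outside its contig", call. = FALSE)
  widths <- ends - starts + 1
  usable <- widths >= length_range[1]
  if (any(!usable))
    warning(sum(!usable), " island(s) shorter than ", length_range[1],
            " nt skipped")
  if (!any(usable)) stop("no usable islands", call. = FALSE)
  chrom <- chrom[usable]; starts <- starts[usable]
  ends <- ends[usable]; widths <- widths[usable]
  with_seed(seed, {
    isl <- sample.int(length(widths), n, replace = TRUE)
    lens <- vapply(isl, function(j)
      sample(length_range[1]:min(length_range[2], widths[j]), 1),
      integer(1))
    offs <- vapply(seq_len(n), function(i)
      sample.int(widths[isl[i]] - lens[i] + 1, 1), integer(1))
    fs <- starts[isl] + offs - 1L
    seqs <- as.character(Biostrings::subseq(contigs[chrom[isl]],
                                            start = fs,
                                            end = fs + lens - 1L))
    oligo_set(seqs,
              paste0("frag_", seq_len(n), "_", chrom[isl], ":", fs, "-",
                     fs + lens - 1L),
              label = "negative", name = "cpg_island_fragments")
  })
}

#' Stratified 80/20 train/validation split
#'
#' Shuffles each class with the seed and assigns the first
#' `floor(train_frac * n)` oligos to training, the remainder to
#' validation; a 2193-positive set at 0.8 yields 1754 training and 439
#' validation positives. Train and validation are disjoint by
#' construction.
#'
#' @param pos,neg labelled `oligo_set`s (each of size >= 2).
#' @param train_frac training fraction in (0, 1).
#' @param seed integer seed.
#' @return a `dataset_bundle`: list with `train_pos`, `train_neg`,
#'   `valid_pos`, `valid_neg`, `ratio`, `seed`.
#' @export
train_valid_split <- function(pos, neg, train_frac = 0.8, seed = 1) {
  stopifnot(inherits(pos, "oligo_set"), inherits(neg, "oligo_set"),
            train_frac > 0, train_frac < 1)
  if (nrow(pos) < 2 || nrow(neg) < 2)
    stop("each class needs at least 2 oligos to split", call. = FALSE)
  split_one <- function(set, s) {
    perm <- with_seed(s, sample.int(nrow(set)))
    n_train <- floor(train_frac * nrow(set))
    list(train = subset_oligo_set(set, sort(perm[seq_len(n_train)])),
         valid = subset_oligo_set(set, sort(perm[-seq_len(n_train)])))
  }
  sp <- split_one(pos, seed)
  sn <- split_one(neg, seed + 1L)
  structure(list(train_pos = sp$train, train_neg = sn$train,
                 valid_pos = sp$valid, valid_neg = sn$valid,
                 ratio = nrow(neg) / nrow(pos), seed = seed),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf(paste0("<dataset_bundle> train %d+/%d-  valid %d+/%d-  ",
                     "ratio %.2g  seed %d\n"),
              nrow(x$train_pos), nrow(x$train_neg),
              nrow(x$valid_pos), nrow(x$valid_neg), x$ratio, x$seed))
  invisible(x)
}

# Concatenate the training (or validation) halves of a bundle into one
# labelled oligo_set, ready for featurize_set()/cross_validate().
#' Combine a bundle's training or validation sets
#'
#' @param bundle a `dataset_bundle`.
#' @param which `"train"`, `"valid"`, or `"all"` (both halves, e.g. for
#'   cross-validating over the full benchmark).
#' @return a labelled `oligo_set`.
#' @export
bundle_set <- function(bundle, which = c("train", "valid", "all")) {
  which <- match.arg(which)
  if (which == "all") {
    out <- rbind(as.data.frame(bundle$train_pos),
                 as.data.frame(bundle$valid_pos),
                 as.data.frame(bundle$train_neg),
                 as.data.frame(bundle$valid_neg))
    rownames(out) <- NULL
    class(out) <- c("oligo_set", "data.frame")
    attr(out, "name") <- "all"
    return(out)
  }
  p <- bundle[[paste0(which, "_pos")]]
  n <- bundle[[paste0(which, "_neg")]]
  out <- rbind(as.data.frame(p), as.data.frame(n))
  rownames(out) <- NULL
  class(out) <- c("oligo_set", "data.frame")
  attr(out, "name") <- which
  out
}

#' Build a realistic (imbalanced) dataset
#'
#' Samples `ratio` negatives per positive from a negative pool without
#' replacement (a 2193-positive set at ratio 10 draws 21930 negatives),
#' then splits both classes 80/20.
#'
#' @param pos positive `oligo_set`.
#' @param neg_pool negative pool (size >= `ratio * nrow(pos)`).
#' @param ratio negatives per positive (default 10; 1 gives a balanced
#'   set).
#' @param seed integer seed.
#' @param train_frac training fraction.
#' @return a `dataset_bundle`.
#' @export
make_realistic <- function(pos, neg_pool, ratio = 10, seed = 1,
                           train_frac = 0.8) {
  stopifnot(inherits(pos, "oligo_set"), inherits(neg_pool, "oligo_set"),
            ratio >= 1)
  n_neg <- ratio * nrow(pos)
  if (nrow(neg_pool) < n_neg)
    stop("negative pool too small: need ", n_neg, ", have ",
         nrow(neg_pool), call. = FALSE)
  neg <- with_seed(seed,
                   subset_oligo_set(neg_pool,
                                    sort(sample.int(nrow(neg_pool), n_neg))))
  train_valid_split(pos, neg, train_frac = train_frac, seed = seed + 1L)
}

#' Palindromic subset of an oligonucleotide set
#'
#' Keeps the oligos containing at least one reverse-complement
#' palindrome of the given minimum length (see [find_palindromes()]);
#' with `strict = TRUE` only wholly palindromic oligos are kept.
#'
#' @param set an `oligo_set`.
#' @param min_len minimum palindrome length (default 6).
#' @param strict whole-sequence palindromes only.
#' @return the filtered `oligo_set`.
#' @export
palindromic_subset <- function(set, min_len = 6, strict = FALSE) {
  stopifnot(inherits(set, "oligo_set"))
  keep <- vapply(set$seq, function(s)
    nrow(find_palindromes(s, min_len, strict)) > 0, logical(1))
  subset_oligo_set(set, keep)
}

#' Write / read a dataset bundle
#'
#' Four FASTA files (train/valid x pos/neg) plus a JSON manifest with
#' counts, ratio and seed.
#'
#' @param bundle a `dataset_bundle`.
#' @param dir directory (created if needed).
#' @return `dir` (write) or a `dataset_bundle` (read).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parts <- c("train_pos", "train_neg", "valid_pos", "valid_neg")
  for (p in parts) write_fasta(bundle[[p]], file.path(dir, paste0(p, ".fa")))
  manifest <- list(counts = lapply(bundle[parts], nrow),
                   ratio = bundle$ratio, seed = bundle$seed,
                   package = "imodn")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  rd <- function(p, label) read_fasta(file.path(dir, paste0(p, ".fa")),
                                      label = label, name = p)
  structure(list(train_pos = rd("train_pos", "positive"),
                 train_neg = rd("train_neg", "negative"),
                 valid_pos = rd("valid_pos", "positive"),
                 valid_neg = rd("valid_neg", "negative"),
                 ratio = manifest$ratio, seed = manifest$seed),
            class = "dataset_bundle")
}
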
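#' Construct an oligonucleotide set
#'
#' An `oligo_set` is the package's container for labelled
#' oligodeoxynucleotides: a data frame with columns `id`, `seq` and
#' `label` (one of `"positive"`, `"negative"`, `"unknown"`). Sequences
#' are validated to the strict A/C/G/T alphabet and uppercased; `U` is
#' mapped to `T` so RNA-style input is accepted.
#'
#' @param seq character vector of DNA sequences.
#' @param id character vector of unique identifiers (default `oligo_1`, ...).
#' @param label class labels, recycled; one of `positive`, `negative`,
#'   `unknown`.
#' @param name a name for the set.
#' @return an object of class `oligo_set`.
#' @examples
#' oligo_set(c("TCGTCGTT", "GGCGGC"), label = c("positive", "negative"))
#' @export
oligo_set <- function(seq, id = NULL, label = "unknown", name = "oligo_set") {
  seq <- normalize_seqs(seq)
  bad <- grep("[^ACGT]", seq)
  if (length(bad))
    stop("sequences outside the A/C/G/T alphabet at positions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(!nzchar(seq))) stop("empty sequences are not allowed", call. = FALSE)
  if (is.null(id))
    id <- if (length(seq)) paste0("oligo_", seq_along(seq)) else character(0)
  if (anyDuplicated(id))
    stop("duplicate ids in set: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  label <- rep_len(as.character(label), length(seq))
  stopifnot(all(label %in% c("positive", "negative", "unknown")))
  out <- data.frame(id = as.character(id), seq = seq, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("oligo_set", "data.frame")
  attr(out, "name") <- name
  out
}

normalize_seqs <- function(seq) {
  chartr("U", "T", toupper(as.character(seq)))
}

#' @export
print.oligo_set <- function(x, ...) {
  cat(sprintf("<oligo_set '%s'> %d oligos (%d positive, %d negative, %d unknown)\n",
              attr(x, "name") %||% "oligo_set", nrow(x),
              sum(x$label == "positive"), sum(x$label == "negative"),
              sum(x$label == "unknown")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an oligonucleotide set from FASTA
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped), uppercases the
#' sequences and maps `U` to `T`. Records containing any other non-A/C/G/T
#' character are rejected; the rejected records are attached as a
#' per-record report (attribute `"rejected"`, a data frame of id, reason)
#' and can be written out with [write_rejects()].
#'
#' @param path path to a FASTA file.
#' @param label label assigned to all records read.
#' @param name set name; defaults to the file name.
#' @return an `oligo_set`; rejected records in `attr(x, "rejected")`.
#' @export
read_fasta <- function(path, label = "unknown", name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- normalize_seqs(as.character(recs))
  bad <- grepl("[^ACGT]", seqs) | !nzchar(seqs)
  rejected <- data.frame(id = ids[bad],
                         reason = vapply(seqs[bad], function(s) {
                           if (!nzchar(s)) return("empty sequence")
                           off <- setdiff(unique(strsplit(s, "")[[1]]), DNA_ALPHABET)
                           paste0("non-ACGT character(s): ", paste(off, collapse = ","))
                         }, character(1), USE.NAMES = FALSE),
                         stringsAsFactors = FALSE)
  out <- oligo_set(seqs[!bad], ids[!bad], label = label, name = name)
  attr(out, "rejected") <- rejected
  out
}

#' Write an oligonucleotide set to FASTA
#'
#' @param set an `oligo_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path) {
  stopifnot(inherits(set, "oligo_set"))
  x <- Biostrings::DNAStringSet(stats::setNames(set$seq, set$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write the per-record rejection report of [read_fasta()] as TSV
#'
#' @param set an `oligo_set` returned by [read_fasta()].
#' @param path output TSV path (columns: id, reason).
#' @return `path`, invisibly.
#' @export
write_rejects <- function(set, path) {
  rej <- attr(set, "rejected") %||%
    data.frame(id = character(), reason = character())
  write.table(rej, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter an oligonucleotide set by length
#'
#' Retains exactly the oligos with `min_len <= nchar(seq) <= max_len`
#' (both bounds inclusive), preserving order. The 5-35 nt default window
#' is the model I/O range used throughout the package.
#'
#' @param set an `oligo_set`.
#' @param min_len,max_len inclusive length bounds.
#' @return the filtered `oligo_set`.
#' @export
length_filter <- function(set, min_len = 5, max_len = 35) {
  stopifnot(inherits(set, "oligo_set"), min_len >= 1, max_len >= min_len)
  keep <- nchar(set$seq) >= min_len & nchar(set$seq) <= max_len
  subset_oligo_set(set, keep)
}

#' Remove exact duplicate sequences
#'
#' Removes exact full-sequence duplicates, keeping the first occurrence;
#' order is otherwise preserved. No similarity-based redundancy reduction
#' is attempted.
#'
#' @param set an `oligo_set`.
#' @return the deduplicated `oligo_set`.
#' @export
dedup <- function(set) {
  stopifnot(inherits(set, "oligo_set"))
  subset_oligo_set(set, !duplicated(set$seq))
}

subset_oligo_set <- function(set, keep) {
  out <- as.data.frame(set)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("oligo_set", "data.frame")
  attr(out, "name") <- attr(set, "name")
  out
}
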
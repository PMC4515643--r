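scorer_T_count <- function(seqs) nchar(gsub("[^T]", "", seqs))

test_that("window scan tiles the query at step 1", {
  seq <- rand_dna(25)
  hits <- window_scan(scorer_T_count, seq, 20)
  expect_equal(nrow(hits), 6)
  expect_equal(hits$start, 1:6)
  expect_equal(hits$end - hits$start + 1, rep(20L, 6))
  expect_equal(hits$window_seq, substring(seq, 1:6, 20:25))
  expect_error(window_scan(scorer_T_count, "ACGT", 5), "longer")
  const <- window_scan(function(s) rep(1, length(s)), seq, 10)
  expect_equal(unique(const$score), 1)
  expect_equal(unique(const$call), "IMODN")
})

test_that("window scan localizes a planted T-rich region", {
  set.seed(35)
  recovered <- 0
  for (rep_i in 1:20) {
    s <- rand_dna(200, prob = c(.3, .3, .3, .1))
    planted_at <- sample(1:(200 - 19), 1)
    substr(s, planted_at, planted_at + 19) <- strrep("TCGT", 5)
    hits <- window_scan(scorer_T_count, s, 20)
    best <- hits$start[which.max(hits$score)]
    if (abs(best - planted_at) < 20) recovered <- recovered + 1
  }
  expect_gte(recovered, 18)  # >= 90% of replicates
})

test_that("analogs form the complete Hamming-1 neighbourhood", {
  a <- generate_analogs("ACG")
  expect_equal(nrow(a), 9)
  expect_equal(a$id[1:3], c("1A>C", "1A>G", "1A>T"))
  set.seed(36)
  s <- rand_dna(20)
  an <- generate_analogs(s)
  expect_equal(nrow(an), 60)
  expect_false(any(an$seq == s))
  expect_equal(length(unique(an$seq)), 60)
  ham <- vapply(an$seq, function(x)
    sum(strsplit(x, "")[[1]] != strsplit(s, "")[[1]]), numeric(1))
  expect_true(all(ham == 1))
  # brute-force neighbourhood: every Hamming-1 neighbour appears
  nb <- character()
  for (i in 1:20) for (nt in c("A", "C", "G", "T")) {
    cand <- s; substr(cand, i, i) <- nt
    if (cand != s) nb <- c(nb, cand)
  }
  expect_setequal(an$seq, unique(nb))
})

test_that("virtual screening ranks analogs by score with the parent first", {
  set.seed(37)
  s <- rand_dna(12)
  tab <- virtual_screen(scorer_T_count, s)
  expect_equal(tab$id[1], "parent")
  expect_equal(nrow(tab), 1 + 36)
  expect_true(all(diff(tab$score[-1]) <= 0))
  expect_equal(max(tab$score[-1]),
               max(scorer_T_count(generate_analogs(s)$seq)))
  const <- virtual_screen(function(x) rep(2, length(x)), s)
  expect_true(all(const$delta == 0))
  # mutating any position to T raises a T-count score
  to_T <- grepl(">T$", tab$id)
  expect_true(all(tab$delta[to_T] > 0))
})

test_that("palindrome finder: canonical examples", {
  hit <- find_palindromes("GAATTC")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$subseq, "GAATTC")
  expect_equal(nrow(find_palindromes("AAAAAA")), 0)
  expect_equal(find_palindromes("TTGAATTCAA")$length, 10L)
  expect_error(find_palindromes("ACGT", min_len = 5), "%%")
  # strict mode: whole-sequence palindromes only
  expect_equal(nrow(find_palindromes("AGAATTCT", strict = TRUE)), 1)
  expect_equal(nrow(find_palindromes("AGAATTCTG", strict = TRUE)), 0)
})

test_that("palindrome finder agrees with the all-substrings oracle", {
  set.seed(38)
  for (i in 1:25) {
    s <- rand_dna(30, prob = c(.3, .2, .2, .3))
    got <- find_palindromes(s, min_len = 4)
    want <- oracle_palindromes(s, min_len = 4)
    expect_equal(got$start, want$start, info = s)
    expect_equal(got$length, want$length, info = s)
    expect_equal(got$subseq, want$subseq, info = s)
  }
})

test_that("palindrome hits are invariant under reverse complementation", {
  set.seed(39)
  for (i in 1:10) {
    s <- rand_dna(25)
    L <- nchar(s)
    fwd <- find_palindromes(s, min_len = 4)
    rev <- find_palindromes(revcomp(s), min_len = 4)
    # map reverse-strand coordinates back to the forward strand
    mapped <- data.frame(start = L - (rev$start + rev$length - 1) + 1,
                         length = rev$length,
                         subseq = revcomp(rev$subseq))
    mapped <- mapped[order(mapped$start, mapped$length), ]
    expect_equal(fwd$start, mapped$start)
    expect_equal(fwd$subseq, mapped$subseq)
  }
})

test_that("digest: single-site, no-site, and multi-enzyme cut-set oracle", {
  eco <- data.frame(name = "EcoRI", site = "GAATTC", offset = 1)
  fr <- digest("AAGAATTCTT", eco)
  expect_equal(fr$seq, c("AAG", "AATTCTT"))
  expect_equal(fr$right_enzyme[1], "EcoRI")
  expect_equal(fr$left_enzyme[2], "EcoRI")
  whole <- digest("ACGTACGT", eco)
  expect_equal(whole$seq, "ACGTACGT")

  set.seed(40)
  enz <- rbind(eco,
               data.frame(name = "DpnII", site = "GATC", offset = 0),
               data.frame(name = "AluI", site = "AGCT", offset = 2))
  for (i in 1:15) {
    s <- paste0(rand_dna(20), "GATC", rand_dna(10), "AGCT", rand_dna(20))
    fr <- digest(s, enz)
    expect_equal(paste(fr$seq, collapse = ""), s)  # conservation
    cuts <- oracle_cut_positions(s, enz)
    expect_equal(fr$end[-nrow(fr)], cuts)
  }
  expect_error(digest("ACGT", data.frame(name = "bad", site = "AXT",
                                         offset = 1)), "invalid")
})

test_that("built-in enzyme table loads and cuts", {
  enz <- load_enzymes()
  expect_true(all(c("EcoRI", "DpnII") %in% enz$name))
  fr <- digest("AAGAATTCTT", enz[enz$name == "EcoRI", ])
  expect_equal(fr$seq, c("AAG", "AATTCTT"))
})

test_that("known-oligo mapping finds exact hits on both strands", {
  hits <- map_known("GGTCGTAGG", oligo_set("TCGTA", "lib1"))
  expect_equal(hits$start, 3)
  expect_equal(hits$strand, "+")
  # reverse-strand hit: revcomp(TCGTA) = TACGA
  rhits <- map_known("GGTACGAGG", oligo_set("TCGTA", "lib1"))
  expect_equal(rhits$strand, "-")
  expect_equal(rhits$start, 3)
  none <- map_known("ACGT", oligo_set("ACGTACGTA", "long1"))
  expect_equal(nrow(none), 0)

  set.seed(41)
  for (i in 1:10) {
    s <- rand_dna(60)
    lib <- oligo_set(vapply(rep(4, 5), rand_dna, ""), paste0("m", 1:5))
    got <- map_known(s, lib)
    want <- do.call(rbind, lapply(1:5, function(j) {
      naive <- function(p) which(vapply(1:(60 - nchar(p) + 1), function(st)
        substr(s, st, st + nchar(p) - 1) == p, logical(1)))
      rbind(
        if (length(naive(lib$seq[j])))
          data.frame(id = lib$id[j], start = naive(lib$seq[j]), strand = "+"),
        if (length(naive(revcomp(lib$seq[j]))))
          data.frame(id = lib$id[j], start = naive(revcomp(lib$seq[j])),
                     strand = "-"))
    }))
    if (is.null(want))
      want <- data.frame(id = character(), start = integer(),
                         strand = character())
    want <- want[order(want$id, want$start, want$strand), ]
    rownames(want) <- NULL
    expect_equal(got, want, info = s)
  }
})
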
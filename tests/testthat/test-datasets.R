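# writes a 2-contig toy genome and island BED into tempfiles
local_toy_genome <- function(env = parent.frame()) {
  set.seed(99)
  fa <- withr::local_tempfile(fileext = ".fa", .local_envir = env)
  bed <- withr::local_tempfile(fileext = ".bed", .local_envir = env)
  chr1 <- rand_dna(300); chr2 <- rand_dna(150)
  writeLines(c(">chr1", chr1, ">chr2", chr2), fa)
  # BED is 0-based half-open: chr1:51-150 (100 nt), chr2:11-40 (30 nt),
  # plus one 3-nt island that must be skipped
  writeLines(c("chr1\t50\t150\tisl1", "chr2\t10\t40\tisl2",
               "chr2\t100\t103\ttiny"), bed)
  list(fa = fa, bed = bed, chr1 = chr1, chr2 = chr2)
}

test_that("CpG-island fragments are island substrings with lengths in range", {
  g <- local_toy_genome()
  expect_warning(
    frags <- fragment_cpg_islands(g$fa, g$bed, n = 40, seed = 4),
    "skipped")
  expect_equal(nrow(frags), 40)
  expect_true(all(nchar(frags$seq) >= 5 & nchar(frags$seq) <= 35))
  expect_true(all(frags$label == "negative"))
  islands <- c(substr(g$chr1, 51, 150), substr(g$chr2, 11, 40))
  contained <- vapply(frags$seq, function(s)
    any(grepl(s, islands, fixed = TRUE)), logical(1))
  expect_true(all(contained))
  # determinism
  same <- suppressWarnings(fragment_cpg_islands(g$fa, g$bed, n = 40, seed = 4))
  expect_identical(as.data.frame(same), as.data.frame(frags))
  other <- suppressWarnings(fragment_cpg_islands(g$fa, g$bed, n = 40, seed = 5))
  expect_false(identical(same$seq, other$seq))
})

test_that("fragment starts and lengths are uniform (chi-square at 10k draws)", {
  fa <- withr::local_tempfile(fileext = ".fa")
  bed <- withr::local_tempfile(fileext = ".bed")
  set.seed(98)
  writeLines(c(">chr1", rand_dna(200)), fa)
  writeLines("chr1\t0\t200", bed)
  frags <- fragment_cpg_islands(fa, bed, n = 10000, length_range = c(5, 35),
                                seed = 6)
  lens <- nchar(frags$seq)
  p_len <- chisq.test(table(factor(lens, levels = 5:35)))$p.value
  expect_gt(p_len, 1e-4)
  # starts are uniform given the length: condition on 20-mers, whose
  # start ranges over 1..181 on a 200-nt island
  starts <- as.integer(sub(".*:(\\d+)-.*", "\\1", frags$id))
  s20 <- starts[lens == 20]
  p_start <- chisq.test(table(cut(s20, breaks = seq(0.5, 181.5, length.out = 12))))
  expect_gt(p_start$p.value, 1e-4)
})

test_that("80/20 split uses floor arithmetic and is disjoint and seeded", {
  pos <- toy_set(vapply(rep(8, 60), rand_dna, ""), "positive")
  neg <- toy_set(vapply(rep(8, 50), rand_dna, ""), "negative")
  b <- train_valid_split(pos, neg, 0.8, seed = 11)
  expect_equal(nrow(b$train_pos), 48)
  expect_equal(nrow(b$valid_pos), 12)
  expect_equal(nrow(b$train_neg), 40)
  expect_equal(nrow(b$valid_neg), 10)
  expect_length(intersect(b$train_pos$id, b$valid_pos$id), 0)
  expect_length(intersect(b$train_neg$id, b$valid_neg$id), 0)
  # floor-arithmetic oracle across sizes (966 mirrors the palindromic set)
  for (n in c(2, 7, 10, 966)) {
    s <- toy_set(vapply(rep(6, n), rand_dna, ""), "positive",
                 ids = paste0("p", seq_len(n)))
    bb <- train_valid_split(s, s, 0.8, seed = 1)
    expect_equal(nrow(bb$train_pos), floor(0.8 * n))
    expect_equal(nrow(bb$valid_pos), n - floor(0.8 * n))
  }
  # the canonical 2193-positive split: 1754 train / 439 validation
  big <- toy_set(vapply(rep(6, 2193), rand_dna, ""), "positive")
  bb <- train_valid_split(big, big, 0.8, seed = 2)
  expect_equal(nrow(bb$train_pos), 1754)
  expect_equal(nrow(bb$valid_pos), 439)
  expect_error(train_valid_split(toy_set("ACGTA"), big), "at least 2")
})

test_that("realistic construction samples ratio negatives per positive without replacement", {
  set.seed(43)
  pos <- toy_set(vapply(rep(10, 30), rand_dna, ""), "positive")
  pool <- toy_set(vapply(rep(10, 400), rand_dna, ""), "negative",
                  ids = paste0("n", 1:400))
  b <- make_realistic(pos, pool, ratio = 10, seed = 3)
  n_neg <- nrow(b$train_neg) + nrow(b$valid_neg)
  expect_equal(n_neg, 300)
  sampled_ids <- c(b$train_neg$id, b$valid_neg$id)
  expect_false(any(duplicated(sampled_ids)))
  expect_true(all(sampled_ids %in% pool$id))
  expect_error(make_realistic(pos, pool, ratio = 20), "too small")
  balanced <- make_realistic(pos, pool, ratio = 1, seed = 3)
  expect_equal(nrow(balanced$train_neg) + nrow(balanced$valid_neg), 30)
})

test_that("palindromic subset agrees with brute-force palindrome containment", {
  expect_equal(palindromic_subset(toy_set(c("GAATTC", "AAAAAA")))$seq,
               "GAATTC")
  expect_equal(nrow(palindromic_subset(oligo_set(character(0)))), 0)
  set.seed(44)
  seqs <- vapply(sample(6:20, 150, TRUE), rand_dna, "")
  got <- palindromic_subset(toy_set(seqs), min_len = 6)$seq
  want <- seqs[vapply(seqs, function(s)
    nrow(oracle_palindromes(s, 6)) > 0, logical(1))]
  expect_equal(got, want)
})

test_that("synthetic positives carry the planted motif at the requested rate", {
  b1 <- synth_benchmark(synth_params(n_pos = 50, n_neg = 5, plant_rate = 1,
                                     seed = 45))
  pos <- c(b1$train_pos$seq, b1$valid_pos$seq)
  expect_true(all(grepl("TCGTCG", pos)))
  b0 <- synth_benchmark(synth_params(n_pos = 400, n_neg = 5, plant_rate = 0.6,
                                     seed = 46))
  rate <- mean(grepl("TCGTCG", c(b0$train_pos$seq, b0$valid_pos$seq)))
  # binomial 3-sigma band around 0.6 (plus rare spontaneous occurrences)
  expect_gt(rate, 0.6 - 3 * sqrt(0.24 / 400))
  expect_lt(rate, 0.6 + 3 * sqrt(0.24 / 400) + 0.05)
})

test_that("generator moments: positives match pos_mono, negatives the chain stationary", {
  p <- synth_params(n_pos = 1000, n_neg = 1000, plant_rate = 0, seed = 47)
  b <- synth_benchmark(p)
  comp_of <- function(set1, set2) {
    seqs <- c(set1$seq, set2$seq)
    colMeans(t(vapply(seqs, function(s) kmer_composition(s, 1), numeric(4))))
  }
  pos_comp <- comp_of(b$train_pos, b$valid_pos)
  expect_lt(abs(pos_comp[["T"]] / 100 - 0.30), 0.015)
  expect_lt(abs(pos_comp[["C"]] / 100 - 0.25), 0.015)
  # negatives follow the CpG-boosted chain; oracle marginal by power
  # iteration, independent of chain_stationary()
  P <- cpg_chain_matrix(p$neg_mono, p$neg_cpg_boost)
  v <- rep(0.25, 4)
  for (i in 1:200) v <- as.numeric(v %*% P)
  neg_comp <- comp_of(b$train_neg, b$valid_neg)
  for (nt in c("A", "C", "G", "T"))
    expect_lt(abs(neg_comp[[nt]] / 100 - v[match(nt, c("A", "C", "G", "T"))]),
              0.02)
  expect_equal(as.numeric(chain_stationary(P)), v, tolerance = 1e-8)
})

test_that("identical class distributions and no motif give a null AUC", {
  p <- synth_params(n_pos = 120, n_neg = 120, plant_rate = 0,
                    pos_mono = c(A = .25, C = .25, G = .25, T = .25),
                    neg_mono = c(A = .25, C = .25, G = .25, T = .25),
                    neg_cpg_boost = 1, seed = 48)
  b <- synth_benchmark(p)
  rep <- cross_validate(bundle_set(b, "train"), feature_k = 1,
                        grid = svm_grid(cost = 1, gamma = 2^-7), folds = 5,
                        seed = 48)
  expect_gt(attr(rep, "auc"), 0.3)
  expect_lt(attr(rep, "auc"), 0.7)
})

test_that("bundles round-trip through FASTA + manifest", {
  b <- synth_benchmark(synth_params(n_pos = 20, n_neg = 20, seed = 49))
  d <- withr::local_tempdir()
  write_bundle(b, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- read_bundle(d)
  for (part in c("train_pos", "train_neg", "valid_pos", "valid_neg")) {
    expect_equal(back[[part]]$seq, b[[part]]$seq)
    expect_equal(back[[part]]$label, b[[part]]$label)
  }
  expect_equal(back$ratio, b$ratio)
})

test_that("generated oligos satisfy alphabet and length invariants; params validate", {
  b <- synth_benchmark(synth_params(n_pos = 80, n_neg = 80, seed = 50))
  all_seq <- c(b$train_pos$seq, b$train_neg$seq, b$valid_pos$seq,
               b$valid_neg$seq)
  expect_false(any(grepl("[^ACGT]", all_seq)))
  expect_true(all(nchar(all_seq) >= 5 & nchar(all_seq) <= 35))
  expect_error(synth_params(pos_mono = c(A = .5, C = .5, G = .5, T = .5)))
  expect_error(synth_params(plant_rate = 1.5))
  expect_error(synth_params(planted_motif = strrep("TCG", 20)), "longer")
  # same seed, same bundle
  b2 <- synth_benchmark(synth_params(n_pos = 80, n_neg = 80, seed = 50))
  expect_identical(as.data.frame(b2$train_pos), as.data.frame(b$train_pos))
})
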
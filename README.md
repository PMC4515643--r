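# imodn

Prediction and design of immunomodulatory oligodeoxynucleotides (IMODNs)
in R.

IMODNs are short single-stranded DNA sequences (5–35 nt), typically
carrying unmethylated CpG motifs, that stimulate innate immunity through
toll-like receptor 9 and are studied as vaccine adjuvants. TLR9
stimulation is sequence-dependent, so telling stimulatory from
non-stimulatory oligonucleotides is a supervised sequence-classification
problem, and improving a candidate oligo is score-guided sequence
editing. `imodn` implements both sides:

* **Features & classifier** — normalized overlapping k-mer composition
  for k = 1..5 (dimensions 4, 16, 64, 256, 1024; each vector sums to
  100%), fed to an RBF-kernel SVM with seeded internal grid selection.
  Evaluation sweeps decision thresholds t ∈ −1..1 and reports
  sensitivity, specificity, accuracy (%) and the Matthews correlation
  coefficient

      MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

  plus the rank-based (Mann–Whitney) AUC. Cross-validation is stratified
  5-fold with pooled held-out scores.
* **Motifs** — mining of discriminative degenerate motifs (literal
  nucleotides with `-` gaps, e.g. `TCGTCG-T`), ranked by per-sequence
  coverage within exclusivity classes (exclusive / relaxed_200/300/400),
  and hybrid scoring: the SVM score ±1 for presence of class motifs.
* **Quantitative matrices** — position-specific frequency-difference
  tables (4×35 mononucleotide, 16×34 dinucleotide), length-normalized
  scoring, and greedy minimal-mutation redesign toward a target score
  (provably minimal for the mononucleotide matrix).
* **Design utilities** — fixed-window scanning of long sequences,
  virtual screening of all 3L single-substitution analogs,
  reverse-complement palindrome search, restriction digest, and exact
  mapping of known oligos on both strands.
* **Datasets** — FASTA I/O with strict A/C/G/T validation, 5–35 nt
  length filtering, deduplication, CpG-island fragmentation of a genome
  into negatives, balanced (1:1) and realistic (1:10) dataset
  construction with seeded 80/20 splits, and a fully synthetic,
  seeded benchmark generator (T-rich positives with a planted `TCGTCG`
  motif vs CpG-island-like negatives).

## Worked example

```r
library(imodn)

# a seeded synthetic benchmark: 200 T-rich positives (60% carry TCGTCG),
# 200 CpG-island-like negatives, lengths 5-35, split 80/20
bundle <- synth_benchmark(synth_params(n_pos = 200, n_neg = 200, seed = 42))
train  <- bundle_set(bundle, "train")
model  <- train_svm(featurize_set(train, k = 5), train$label,
                    seed = 42, feature_k = 5)

motifs <- mine_motifs(bundle$train_pos, bundle$train_neg, max_shared = 0)
head(motifs, 3)
#>     motif pos_coverage neg_coverage     class
#> 1 TCGTCGT           33            0 exclusive
#> 2 TCGTCGG           29            0 exclusive
#> 3 CTC-TCG           25            0 exclusive
```

The top exclusive motifs are one-letter extensions of the planted
`TCGTCG` (the bare motif also occurs in a few CpG-rich negatives by
chance, so it is not *exclusive*); each covers the stated number of
positive training sequences and zero negatives. Attaching the Top10 to
the model adds +1 to the score of any oligo matching one of them:

```r
model  <- attach_motifs(model, top_n_by_coverage(motifs, 10))
valid  <- bundle_set(bundle, "valid")
report <- threshold_sweep(hybrid_score(model, valid), valid$label)
best_row(report)
#>   threshold  sen spec   acc       mcc     auc
#> 1       0.3 67.5  100 83.75 0.7137464 0.94625
```

On the 40+40 held-out oligos the hybrid model's best threshold (0.3)
gives 67.5% sensitivity at 100% specificity, MCC 0.71, and a
threshold-free AUC of 0.946 — short 5–8 nt oligos carry little signal,
which bounds what any classifier can do on these conditions (see the
methods vignette).

Redesign a GC-rich non-stimulatory oligo with the mononucleotide
quantitative matrix, and scan for palindromes:

```r
qm <- build_qm(bundle$train_pos, bundle$train_neg, k = 1)
qm_min_mutations(qm, "GGCCGGCCGG", target = 0.05)
#> <mutation_plan> 4 mutation(s), score -0.0697 -> 0.0713 (target 0.0500, met)
#>   position from to  score_after
#> 1        5    G  T -0.030228407
#> 2       10    G  T  0.007113081
#> 3        2    G  T  0.039829130
#> 4        4    C  T  0.071310612

find_palindromes("TTGAATTCAA")
#>   start length     subseq
#> 1     1     10 TTGAATTCAA
```

Four T-substitutions push the QM score above the target; the palindrome
finder reports the whole query (it equals its own reverse complement).

A command-line interface covering every stage (train / evaluate /
predict / scan / screen / qm-build / qm-score / qm-design / motifs /
palindrome / digest / map / makedata / synth) ships as a thin launcher:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "imodn.R", package = "imodn"))')" \
    synth --out data/ --seed 1
```

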
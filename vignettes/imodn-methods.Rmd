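---
title: "Predicting and designing immunomodulatory oligodeoxynucleotides with imodn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and designing immunomodulatory oligodeoxynucleotides with imodn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imodn)
```

## The problem

Immunomodulatory oligodeoxynucleotides (IMODNs) are short single-stranded
DNA sequences — typically 5–35 nt and rich in unmethylated CpG motifs —
that activate innate immunity through toll-like receptor 9 (TLR9). They are
of practical interest as vaccine adjuvants. Because TLR9 stimulation is
sequence-dependent, the discrimination between stimulatory and
non-stimulatory oligonucleotides can be cast as a supervised sequence
classification problem, and the design of new IMODNs as score-guided
sequence editing.

`imodn` implements that stack end to end: composition features, an SVM
classifier with threshold-swept evaluation, discriminative degenerate-motif
mining, hybrid motif-weighted scoring, position-specific quantitative
matrices with minimal-mutation redesign, and a set of sequence-design
utilities (window scan, virtual screening, palindrome search, restriction
digest, exact mapping). A seeded synthetic-data generator provides a
controlled benchmark for all of it.

## Features and classifier

Every oligo is represented by its overlapping k-mer composition for a
single k in 1..5 (mono- to pentanucleotide composition). The entry for
word $w$ is

$$x_w = 100\cdot\frac{\#\{\text{occurrences of } w\}}{L-k+1},$$

so a vector always sums to 100 regardless of sequence length, and the
feature dimension is $4^k$ (4, 16, 64, 256, 1024). The denominator
$L-k+1$ (rather than $L$) is chosen precisely so that the normalization
is exact; both percentage and fraction bases are available, and the basis
is fixed per model.

Classification uses a C-SVM with an RBF kernel (via `e1071`/libsvm).
Hyperparameters are selected from a small grid — cost $\{1, 16\}$,
kernel width $\gamma \in \{2^{-11}, 2^{-9}, 2^{-7}\}$ — by seeded internal
cross-validation, maximizing MCC of the raw decision scores at threshold
0. The width grid is deliberately small-valued: the pentanucleotide
representation has 1024 percentage-scale columns, and widths much above
$2^{-7}$ collapse the RBF similarity between sparse high-dimensional
composition vectors, which measurably destroys performance; widths below
$2^{-11}$ approach a linear kernel with no further gain. Features are not
re-standardized inside the SVM (`scale = FALSE`): compositions already
share a common scale across sequences, and per-column standardization of
mostly-zero pentanucleotide columns would amplify noise.

Evaluation follows the threshold-sweep convention: predictions are
positive when the decision score is at least $t$, for $t$ on a grid of
$-1$ to $1$ in steps of $0.1$ (the natural scale of SVM margins), and each
row reports sensitivity, specificity and accuracy in percent plus the
Matthews correlation coefficient,

$$\mathrm{MCC}=\frac{TP\cdot TN - FP\cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

with the convention $\mathrm{MCC}=0$ when any denominator factor
vanishes (a degenerate predictor carries no correlation). The
threshold-free AUC is the rank-based Mann–Whitney statistic: the
probability that a random positive outscores a random negative, ties
counted half.

Cross-validation is stratified k-fold (default 5) with seeded fold
assignment. Held-out decision scores are pooled across folds and swept
once, rather than averaging per-fold metric tables: pooling yields one
coherent ROC, is deterministic given the seed, and avoids averaging
artifacts at extreme thresholds. Class-imbalanced ("realistic," 1:10)
training can enable per-class error weights proportional to inverse class
frequency.

## Degenerate motifs and hybrid scoring

A degenerate motif is a sequence of literal nucleotides and gap markers,
written e.g. `TCGTCG-T`. A gap marker spans 1 to `gap_max` arbitrary
nucleotides (default `gap_max = 1`); a run of $g$ markers spans
$g..g\cdot$`gap_max`. Requiring the gap to consume at least one position
is what distinguishes `TCGTCG-T` from plain `TCGTCGT`, and is the reading
under which listing both forms as distinct motifs makes sense. Motifs
must begin and end with literals.

Mining enumerates every literal word of 3–10 nt occurring in the positive
set, plus single-gap joins of pairs drawn from the 25 highest-coverage
literal words (total literal length at most 10). Coverage is counted per
sequence — a sequence contributes at most one count no matter how many
occurrences it contains. Candidates matching more than `max_shared`
opposing-set sequences are discarded; `max_shared` of 0, 200, 300, 400
defines the exclusivity classes *exclusive*, *relaxed_200*, *relaxed_300*,
*relaxed_400*. Survivors are ranked by positive coverage, ties broken by
shorter text form and then lexicographically, which makes Top10/Top20
extraction deterministic. Mining the negative-discriminating direction is
the same call with the sets swapped. IUPAC class symbols (purine/
pyrimidine letters) are intentionally not part of the candidate space:
keeping the space literal+gap keeps every mined motif's coverage exactly
recountable, which the test suite exploits.

Hybrid scoring adds $+1$ to an oligo's SVM decision score if any
positive-class motif matches and $-1$ if any negative-class motif matches
(both may apply, netting zero). The adjustment is applied to the score
*before* thresholding, so a single threshold governs plain and hybrid
models alike.

## Quantitative matrices and redesign

The quantitative matrix (QM) contrasts per-position word frequencies
between classes. For word $w$ at position $i$ (1-based),

$$\mathrm{QM}[w,i] = f^{+}(w,i) - f^{-}(w,i),\qquad
f(w,i)=\frac{c(w,i)+p}{n_i+4^k p},$$

where $c(w,i)$ counts sequences with word $w$ at position $i$, $n_i$
counts the sequences long enough to have position $i$, and $p$ is a
pseudocount (default 0.5). The mononucleotide matrix is $4\times 35$, the
dinucleotide matrix $16\times 34$ (maximum length 35). A frequency
*difference* rather than a log-odds ratio is the default because it is
bounded, defined when a frequency is zero, and exactly antisymmetric under
swapping the two sets — a property the tests verify literally; log-odds is
available as an option. A sequence's QM score is the *mean* entry over the
positions it occupies, so 5-mers and 35-mers share one threshold scale;
positions a short sequence lacks contribute nothing.

Minimal-mutation redesign (`qm_min_mutations`) greedily applies the
single substitution that moves the score furthest toward the target, ties
resolved leftmost-position-first then alphabetically. For the
mononucleotide matrix, position contributions are independent, so the
greedy plan is provably of minimal length — the suite confirms this
against exhaustive search over all $4^6$ sequences on 6-mers. The default
direction is upward (toward IMODN), with an empty plan when the score
already meets the target; downward design (`direction = "down"`) and a
sign-inferred mode (`"auto"`) cover the reverse case. An unreachable
target is reported in the plan rather than raised as an error.

## Sequence-design utilities

* **Window scan** tiles a query with a fixed window at step 1 and scores
  each window with a model (hybrid score if motifs are attached),
  mapping immunomodulatory regions of longer DNA.
* **Virtual screening** scores the complete Hamming-1 neighbourhood of a
  parent oligo — exactly $3L$ analogs, ids like `5C>T` — and ranks by
  score with the score change versus the parent.
* **Palindrome search** reports maximal even-length substrings equal to
  their own reverse complement (the DNA-biology sense, e.g. `GAATTC`),
  minimum length 6 by default. Only gap-free reverse-complement
  palindromes are considered. "Contains a palindrome" is the default
  criterion for palindromic subsets; a strict whole-sequence mode exists
  because the field uses both senses.
* **Digest** cuts at every forward-strand occurrence of each recognition
  site at its cut offset; fragments concatenate exactly to the input.
  For the palindromic sites of the small built-in table (EcoRI, BamHI,
  HindIII, DpnII, AluI) forward-strand cutting coincides with
  double-strand digestion.
* **Mapping** finds exact occurrences of library oligos on both strands.
  Exact substring matching (not BLAST) keeps the operation dependency-free
  and reproducible; wholly palindromic oligos legitimately report a hit on
  both strands at the same start.

Coordinates in all user-facing output are 1-based inclusive.

## Datasets and the synthetic benchmark

Real training data enter as FASTA; validation uppercases sequences, maps
RNA-style `U` to `T`, and rejects any other non-A/C/G/T record into a
per-record report — downstream features assume a strict 4-letter
alphabet, so ambiguity codes are refused rather than guessed. Length
filtering to 5–35 nt and exact-sequence deduplication reproduce the usual
curation of ODN collections (deduplication is exact-match only; no
similarity-based redundancy reduction is attempted). Negatives can be cut
from CpG islands of a user-supplied genome (FASTA + BED): island chosen
uniformly, fragment length uniform over 5–35 (optionally length-matched to
the positives to avoid a length-confounded classifier), start uniform
within the island. Splits are stratified, seeded, and use floor
arithmetic — 80% of 2193 positives is 1754 training and 439 validation
sequences; 966 palindromic positives split 772/194. Realistic (1:10)
datasets sample ten negatives per positive from a pool without
replacement.

The synthetic benchmark emulates the structure of curated IMODN data:

| parameter | default | meaning |
|---|---|---|
| `n_pos`, `n_neg` | 400 / 400 | set sizes |
| `length_range` | 5–35 nt | uniform oligo lengths |
| `pos_mono` | A .22, C .25, G .23, T .30 | positive base composition (T-rich) |
| `neg_mono` | A .25, C .34, G .25, T .16 | negative base composition (C-rich, T-poor) |
| `planted_motif` | `TCGTCG` | canonical stimulatory motif |
| `plant_rate` | 0.6 | fraction of positives carrying it |
| `neg_cpg_boost` | 4 | C→G transition enrichment of negatives |

Positives are i.i.d. draws from `pos_mono` with the motif overwritten at
a uniform position in the planted fraction; sequences selected for
planting draw their length from at least the motif length, and the motif
must fit `length_range`'s maximum. Negatives follow a first-order chain
whose C-row multiplies the C→G transition by `neg_cpg_boost` and
renormalizes — a minimal model of CpG-island text. Renormalizing the
C-row necessarily shifts the chain's stationary marginal slightly away
from `neg_mono` (realized T ≈ 12.5% rather than 16% at boost 4);
`chain_stationary(cpg_chain_matrix(...))` returns the realized marginal,
and the tests check the generator against that quantity, not against the
nominal vector.

What the generator does *not* emulate: the heavy redundancy of
patent-derived collections (near-duplicate sequences), backbone
chemistry, length–class correlations, and any higher-order sequence
structure beyond first-order CpG enrichment. Benchmarks on it therefore
demonstrate that the machinery recovers planted signal under controlled
conditions — not field performance on literature data.

Two properties of the default conditions are worth knowing before
interpreting benchmark numbers. First, with lengths uniform on 5–35 a
substantial fraction of oligos are 5–8 nt and carry very little
compositional signal, which caps the separability of the two classes well
below perfection regardless of the learner; cross-validated MCC around
0.7–0.76 and AUC around 0.94 for pentanucleotide features are what the
conditions support, with mononucleotide features trailing (directionally
mirroring the mono-to-penta improvement seen on real data). Second, the
CpG-boosted negatives occasionally contain the planted motif by chance
(a handful per 320 training negatives), so `TCGTCG` is typically *not*
exclusive on benchmark data — the exclusive miner instead surfaces its
one-letter extensions (`TTCGTCG`, `TCGTCGG`, ...), while mining under
`max_shared = 200` recovers `TCGTCG` itself at full coverage. Both are
correct behaviour of the miner, verified by brute-force coverage
recounts.

## Numerical and reproducibility choices

Every stochastic step (generation, fold assignment, splits, fragment
sampling) flows from explicit integer seeds through an RNG-state-
preserving wrapper, so seeded end-to-end runs are byte-identical — the
suite asserts this on the full synth→train→evaluate pipeline. Grid and
threshold ties resolve to the first/smallest candidate; motif ranking
ties resolve shorter-then-lexicographic; mutation-plan ties resolve
leftmost-then-alphabetic. Degenerate inputs have defined behaviour:
MCC 0 on degenerate confusion factors, errors on single-class AUC/SVM
input, reported (not raised) unmet redesign targets, empty motif tables
when nothing discriminates.

Problem sizes used by the shipped tests and the acceptance script —
400+400 benchmark oligos, five seeds, five folds, 6-mer exhaustive
redesign checks — were chosen as the smallest sizes at which the
statistical assertions are stable.

## Limitations

Sequence-only modelling: backbone chemistry and modified bases are out of
scope (modified-base records are rejected at I/O). The motif miner's
candidate space is literal words plus gap joins; it does not score motif
significance, and coverage-based ranking favours frequent motifs over
surprising ones. Mapping is exact-substring only. Numeric results
published for the original patent-derived collections are not
reproducible here because those data are not redistributable; the
package's claims are therefore structural and benchmark-based.
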
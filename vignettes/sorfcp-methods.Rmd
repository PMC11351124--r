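---
title: "Classifying small ORFs by coding potential: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying small ORFs by coding potential: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sorfcp)
```

## The problem

Small open reading frames (sORFs; under 100 amino acids, under ~300 nt) are
abundant in every genome, and ribosome profiling keeps finding them engaged
by the translational machinery in supposedly non-coding space — lncRNAs,
UTRs, introns, intergenic DNA. Deciding which of those candidates actually
encode micropeptides is hard: they are short, poorly conserved, and often
recently evolved, so alignment- and conservation-based coding-potential
scores are weak exactly where the question matters. `sorfcp` takes the ab
initio route: classify a candidate sORF as coding or non-coding from its
sequence alone, using the two signals that translation itself leaves in the
DNA — the nucleotide context around the start codon and the codon
composition of the reading frame.

## The representation

Each candidate is an upstream flank plus an ORF running from a start codon
(`ATG` by default) through a stop codon. Two feature families are extracted:

* **TIS (translation initiation site), 36 values.** The 9 nt at positions
  −7..−1 and +4..+5, with the start codon occupying +1..+3 and excluded so
  that start-codon usage cannot leak into the feature. Each position is
  one-hot encoded with the maximal-Hamming-distance code A=0001, C=0010,
  T=0100, G=1000. Positional convention: there is no position 0; "−7 to +5
  excluding the start codon" therefore yields exactly 7 + 2 = 9 positions,
  the only reading consistent with a 36-element vector.
* **CC (coding composition), 64 values.** In-frame (step-3) 3-mer
  frequencies over a fixed window of the ORF body: 54, 99 or 180 nt,
  beginning right after the start codon (offset 3) — or after +93 when the
  signal-peptide skip is enabled — and never overlapping the stop codon.
  The stop codon is excluded deliberately: stop content is a trivially
  label-leaking three-class signal. Frequencies (counts divided by the
  number of 3-mers) are the default; raw counts remain available as an
  ablation flag.

Their concatenation is the 100-dimension **CP (coding potential)** vector.
One classifier is trained per CC window; at prediction time each record is
routed to the longest window that fits (`length(orf) − 6 ≥ window`), which
is also why records shorter than 60 nt of body (< 19 codons beyond start
and stop, i.e. below the 54-nt window) cannot be scored and are reported as
exclusions rather than silently dropped.

## Classifiers, calibration, and one deliberate deviation

Hyper-parameters for SVM (kernel, C, gamma), k-NN (k, vote weighting,
neighbour search) and random forest (trees, split criterion, features per
split) are searched exhaustively with stratified 10-fold cross-validation;
ties resolve by highest mean accuracy, then lowest accuracy variance, then
grid order, so model selection is deterministic. The selected combination
is refit on the full training split and Platt-calibrated — the sigmoid
`P(coding | d) = 1/(1 + exp(A d + B))` is fitted by the robust
prior-corrected Newton procedure on a validation split that is machine-
checked to be disjoint from training. Calibration is monotone, so it
re-scales scores into [0, 1] without ever reordering records.

No SVM or random-forest implementation ships with this environment's R
stack, so both are implemented in compiled code inside the package: the SVM
dual is solved by SMO with second-order working-set selection on a
BLAS-precomputed kernel matrix (deterministic — no randomness, ties to the
lowest index), and the forest is standard bootstrap-aggregated CART with
gini/entropy split quality and an explicitly seeded RNG stream. k-NN uses
the FNN package's neighbour search with uniform or inverse-distance votes.

**The deviation:** the feature blocks are z-scaled column-wise before any
distance-based learner sees them, with the scaler fitted on training data
and stored inside the model. The original design called for unscaled
features on the grounds that both blocks are bounded in [0, 1], but bounded
is not balanced: squared distances between TIS blocks are of order 10 while
CC frequency blocks differ by order 0.05, so an RBF kernel on the raw CP
vector is effectively TIS-only — measurably costing ~25 accuracy points on
synthetic data with a strong codon signal. Tree models are unaffected
either way (per-feature monotone transforms do not change splits);
`standardize = FALSE` restores the raw behaviour for ablation.

## Dataset construction

Positives come from annotated CDS records: genes with a single isoform form
the training positives (no alternative-start ambiguity); for multi-isoform
genes only the longest isoform (ties broken by smallest record id) enters
the simulated evaluation positives, keeping the two sets disjoint by gene.

Negatives are pseudo-ORFs from intergenic space. The gene intervals are
complemented per contig; 2,000 nt immediately upstream of every gene
(strand-aware) are masked to keep promoters out; the remaining intervals
are partitioned by length — the closed interval [20 kb, 50 kb] feeds the
training pool and > 50 kb the simulated pool, disjoint by construction.
Within the pooled sequence, every ATG is extended to the first in-frame
stop; candidates with total length inside the configured bounds are sampled
without replacement under a fixed seed, each with up to 100 nt of upstream
genomic flank. The length bounds default to (60, 450) nt: the source
procedure states an achieved mean of ~210 nt but not the mechanism, so the
bounds are an explicit stand-in and the achieved mean is logged for tuning.
Intervals are held internally as `GRanges` (1-based, closed) — the
Bioconductor convention — with BED (0-based half-open) and GFF3 (1-based
closed) converted at the file boundary; round-trips through either format
restore the original coordinates exactly.

The canonical 60/20/20 train/validation/test split is stratified by label
with floor allocation and remainders to train, so 16,200 labelled examples
yield exactly 9,720/3,240/3,240 with the class ratio preserved.

## What the synthetic generator emulates — and what it does not

The generator produces the statistical contrast the real datasets embody:

* **Coding records:** body codons i.i.d. from
  `signal_strength * codon_usage + (1 − signal_strength) * uniform`, a
  human-like codon-usage table by default; the 9 TIS positions are drawn
  from `signal_strength * kozak_profile + (1 − signal_strength) *
  background`, where the default profile mirrors the published vertebrate
  initiation-context composition (purine, mostly A, at −3; G at +4;
  C-leaning upstream). Mixing the TIS profile by `signal_strength` — not
  only the body — is required for the null world to be truly null: at
  `signal_strength = 0` coding and non-coding records are statistically
  identical in every extracted feature, which is what makes the chance-
  accuracy acceptance band meaningful.
* **Non-coding records:** ATG-anchored background sequence extended to the
  first in-frame stop, constrained to the configured length range. This is
  implemented by the distribution-equivalent direct sampler — body-codon
  count from the range-truncated geometric with the background's per-codon
  stop probability, body codons from the stop-conditioned background codon
  distribution — rather than literal draw-and-reject, which needs unbounded
  retries when the length range sits far in the geometric tail.
* **Mini-genomes:** background contigs with planted genes and a truth
  manifest, alternating intergenic stretches of chosen lengths with coding
  ORFs, so interval logic (complement, promoter masking, size classes) can
  be asserted against planted truth exactly.

Defaults are frozen: uniform background (intergenic space idealized as
"near-uniform"), human-like codon usage, 20–100 aa lengths, 100-nt flanks.
The generator does **not** simulate splicing, Ribo-Seq coverage, FLOSS or
ORFscore distributions, conservation, GC heterogeneity, or repeat content.
A green synthetic test therefore establishes that the pipeline recovers a
planted codon-usage + Kozak contrast — not that real-genome accuracy will
match; real intergenic DNA differs from coding DNA far more strongly than
this idealized null.

One consequence is documented openly: under these frozen defaults the
54-nt window is information-limited. The generator's likelihoods are known
in closed form, so the Bayes-optimal accuracy is computable — about 0.87
for CP54 (0.93 for CP99, 0.97 for CP180; recomputed by the acceptance
suite). No classifier can reach 0.90 on 18 codons of human-vs-uniform usage
plus a 9-nt initiation context, so the pipeline-recovery acceptance
criterion is met by the 99- and 180-nt models and stays honestly red for
the 54-nt model, with the ceiling computed alongside as evidence.

## Numerical and policy choices

* Calling rule: `score > threshold` — strictly greater, so a score exactly
  at the threshold is non-coding. Default 0.5; 0.9 is the high-precision
  mode, and precision at 0.9 ≥ precision at 0.5 is asserted on unbalanced
  synthetic data.
* Undefined confusion ratios (0/0) are reported as `NA`, never 0; report
  denominators count only records with a value for the metric at hand.
* Signal-peptide skip (+90 nt) is off at prediction and off by default in
  the synthetic harness — generated sORFs carry no signal peptide and are
  mostly too short to survive the skip; for real full-length protein
  training sets it should be turned on, symmetrically for both classes.
* SMO stops at a 1e-3 KKT violation gap or 200,000 iterations; Platt's
  Newton stops at gradient 1e-5 with backtracking line search; the kernel
  matrix is built by BLAS and cached per fit.
* Model files are JSON text with a format version; numeric blobs are
  written as full-precision ("%.17g") decimal strings because 15-digit
  JSON numbers would break the bit-identical score round-trip the tests
  assert. Loading a file with a different version is an error.
* External-metric cutoffs (FLOSS 0.26 lower-is-positive; ORFscore 6.044,
  PhyloP 1.0, PhastCon 0.5 higher-is-positive) are registry defaults in the
  spirit of the tools' reference usage, always user-overridable, and are
  configuration — not measured facts.
* All randomness flows through explicit seeds (R's RNG for generation and
  splits, a seeded mt19937 stream inside the forest), and RNG state is
  restored after every seeded call, so end-to-end runs are byte-
  reproducible.

## Limitations

Scores are calibrated probabilities only with respect to the training
contrast; applying a model trained on one organism or one negative model to
another shifts calibration. The TIS feature assumes the provided upstream
flank is the biologically relevant context (transcript-spliced versus
genomic upstream sequence is the caller's responsibility; the benchmark
table's `upstream` column is taken as given). Near-cognate start codons are
supported only via the configurable start-codon set, and no amino-acid,
hexamer, or conservation features are used — by design.
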
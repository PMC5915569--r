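---
title: "Predicting RNA 5-methylcytosine sites with a balanced random-forest ensemble"
author: "m5Cforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA 5-methylcytosine sites with a balanced random-forest ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m5Cforest)
```

# The problem

5-methylcytosine (m5C) is a post-transcriptional modification of cytosine in
RNA, implicated in RNA localization, stability and translational fidelity.
RNA bisulfite sequencing can map m5C at single-nucleotide resolution —
unmethylated cytosines deaminate to uracil and are read as T, methylated
cytosines resist conversion — but it only captures a snapshot of expressed
transcripts under one condition. A sequence-based predictor generalizes those
snapshots: it learns what the flanking sequence of methylated cytosines looks
like and scores every cytosine of a transcriptome.

`m5Cforest` implements such a predictor end to end: training-set construction
from per-cytosine bisulfite counts, three sequence encodings, an ensemble of
ten random forests built for the 1:10 class imbalance, a window/feature
optimization loop, specificity-anchored confidence thresholds, and
transcriptome-wide annotation (sequence context, mRNA region, distance to the
translational start).

# From counts to a labeled training set

Per-cytosine methylation is estimated with the pseudo-count proportion
statistic

$$P = \frac{C + \Psi}{T + C}, \qquad \Psi = \tfrac{1}{8},$$

where $C$ and $T$ count reads supporting the methylated and converted state.
A cytosine is called **positive** when $P \ge 1\%$ and its FDR $\le 0.3$,
both boundaries inclusive. The FDR column may be supplied by the user;
when absent, `addSiteFDR()` derives one-sided binomial p-values against a
configurable non-conversion error rate (default 0.005) and adjusts them with
Benjamini–Hochberg. The binomial route is a self-contained convenience —
the statistic behind externally supplied q-values is the caller's business —
and is flagged as such in the function documentation.

Each sample is a 43-nt window centered on its cytosine; flank positions
beyond the transcript ends are filled with `N`, but a site whose own central
base would be padded is rejected. For every positive, up to 10 **GC-matched
negatives** are drawn uniformly at random from the unmethylated cytosines
within ±100 nt whose window GC content differs by at most 5 percentage
points; this prevents the learner from keying on composition bias. GC is
computed over the same 43-nt window as the sample itself — matching "around
the positive" admits either a window-level or a regional reading, and the
window-level one is the testable choice. When fewer than 10 candidates
qualify, all are taken and a shortfall warning is raised.

# Feature encoding

An $L$-nt window is encoded as a vector of $4L + 106$ named features:

* **Binary** ($4L$): per position, A→(1,0,0,0), C→(0,1,0,0), G→(0,0,1,0),
  U→(0,0,0,1), N→(0,0,0,0). The constant central C is retained; feature
  selection discards constants on its own.
* **k-mer** (84): frequencies of all 4, 16 and 64 k-mers for $k = 1,2,3$,
  each count divided by the number of k-length substrings free of `N`.
* **PseDNC** ($16 + \lambda$): type-I pseudo dinucleotide composition. The
  16 adjacent-dinucleotide frequencies $f_u$ and $\lambda$ pseudo components
  $\theta_j$ — the mean squared difference of standardized physicochemical
  property vectors between dinucleotides $j$ apart — are combined as
  $d_u = f_u / (1 + w\sum\theta)$ and
  $d_{16+j} = w\,\theta_j / (1 + w\sum\theta)$, so the block is non-negative
  and sums to 1. Defaults: $\lambda = 6$ (forced arithmetically by the
  $4L + 106$ total), $w = 0.1$. Dinucleotides containing `N` are skipped in
  both sums, and a separation $j$ with no dinucleotide pair inside the
  window contributes $\theta_j = 0$ — so the vector keeps its $16 + \lambda$
  shape (and the total its $4L + 106$) even for the shortest 5-nt windows
  of the optimization sweep.

The packaged property table holds the RNA nearest-neighbour thermodynamic
parameters of the Turner rules (Xia et al. 1998): stacking free energy at
37 °C, enthalpy, and the entropy they jointly imply; each dinucleotide takes
the value of its Watson–Crick stack and each property is standardized to
mean 0, sd 1 across the 16 dinucleotides before use. Any table with 16 rows
and named numeric columns can be substituted via `readPropertyTable()`; we
ship the thermodynamic set because its values are unambiguous in the
literature, whereas published structural parameter sets for RNA dinucleotides
vary between sources.

# The ensemble learner

Training sets are imbalanced by construction (1:10). Rather than reweighting,
the negatives are shuffled and split into ten near-equal parts; forest $i$
(100 trees, bootstrap resampling, $\sqrt{p}$ features per split, unlimited
depth) trains on **all** positives plus part $i$. A sample's score is the
mean of the ten forests' positive-class probabilities — continuous scores
are required because the confidence thresholds sit at arbitrary
specificities; a hard majority vote would not support them.

Model assessment and threshold calibration use stratified 10-fold
cross-validation: the reported AUC is the mean of the ten per-fold AUCs, and
the pooled out-of-fold scores feed `determineThresholds()`. For each target
specificity $s \in \{0.99, 0.95, 0.90, 0.85\}$ (modes VH/H/N/L), the
threshold is the smallest observed negative score $t$ with
$\widehat{F}^-(t) \ge s$, the empirical quantile with higher interpolation;
pooling out-of-fold scores (rather than averaging per-fold quantiles) keeps
the construction exact and monotone. Classification is strict: a site is
positive iff its score exceeds the threshold, so the calibrated specificity
is guaranteed on the calibration scores up to the quantile's one-count
discreteness. Thresholds transfer to new data only as well as the training
negatives represent it — on a different negative distribution the achieved
specificity will drift, which is the usual caveat of anchored thresholds.

# Window and feature optimization

`optimizeModel()` sweeps window length $L$ (default 5–43 nt) and, within
each $L$, every upstream flank $L_u \in 1..L-2$ (with $L_d = L - 1 - L_u$).
Features are ranked by **information gain** — the entropy reduction of the
label given the feature, discretized into ten equal-frequency bins
(binary indicators are used as-is; ties keep canonical feature order) — and
the feature count $F$ is swept over a geometric grid $2, 4, 8, \dots, p$
(`exhaustive = TRUE` restores the full integer sweep from 2 to $4L + 106$).
Each grid point is scored by 10-fold cross-validated AUC; the per-geometry
maximum is stored and the overall argmax returned. By default the ranking is
computed once per geometry on the full optimization dataset, mirroring the
optimization loop's published shape; `leakageFree = TRUE` re-ranks inside
every training fold for a selection-leakage-free estimate, at ten times the
ranking cost.

# The synthetic transcriptome

Every claim the test suite makes is backed by `simulateDataset()`. It draws
transcripts i.i.d. from a background composition (default uniform), plants a
CDS across the middle 60% of each transcript (with an AUG start codon, so
region and start-distance annotation are exercised), and plants positives at
randomly chosen cytosines. The flanks of each planted site (±5 nt by
default) are redrawn from an interpolated base distribution
$(1-\varepsilon)\,\text{background} + \varepsilon\,\text{target}$, where the
target puts weight 0.9 on G — a single interpretable effect-strength knob
$\varepsilon$ emulating the G-enrichment observed around genuine m5C sites.
An optional context mix forces the two downstream bases of planted sites
into programmed CG/CHG/CHH proportions. `simulateBisulfiteCounts()` lays a
negative-binomial coverage model (mean 100, dispersion 5) over every
cytosine and draws C-counts binomially: planted level (default 0.3) at truth
sites, non-conversion error (default 0.005) elsewhere.

What the generator does **not** emulate: real m5C motifs beyond a univariate
G bias, transcript-family sequence redundancy, expression-dependent
coverage, splice isoforms, or read-level artifacts. Passing the recovery
tests therefore demonstrates that the machinery is correct and sensitive to
a planted signal of realistic shape — not that the packaged defaults attain
any particular accuracy on real bisulfite data, whose signal strength is
fixed by biology, not by $\varepsilon$.

# Numerical choices and edge cases

* Coordinates are 0-based half-open internally; every emitted TSV is
  1-based. GFF3 is ingested as 1-based inclusive via `rtracklayer`, exons
  spliced, CDS mapped into transcript space, minus strands
  reverse-complemented.
* Distance to the translational start is `position − cdsStart + 1`: the A of
  AUG is +1, the C of AUG·C is +4, upstream positions are negative.
* Sequence context needs the two bases 3′ of the site; `CG` can be called
  from one. `N` or a transcript end makes the context `NA`, and such sites
  are excluded from (and do not distort) context proportions.
* AUC is computed in the rank/Mann–Whitney form with midrank tie handling;
  the precision–recall area uses right-continuous steps with no precision
  interpolation. Both are verified against brute-force oracles in the test
  suite.
* Per-metric zero denominators yield `NA` (undefined), never 0.
* All randomness — simulation, negative sampling, fold assignment, forest
  construction — flows from explicit integer seeds; per-forest seeds are
  derived deterministically, and identical configurations reproduce outputs
  byte for byte.
* Degenerate inputs fail loudly: zero coverage, single-class labels, empty
  windows, feature-name mismatches and unknown confidence modes are errors,
  not silent zeros.

# Scale of the shipped experiments

The test suite and the acceptance script run the recovery experiments at
500 planted positives with roughly ten GC-matched negatives each (about
5,500 samples), 11-nt windows, 150 features, 10-fold cross-validation, and
three signal strengths $\varepsilon \in \{0, 0.5, 1\}$ — sizes chosen so the
stochastic assertions (null AUC within [0.45, 0.55], strong-signal AUC at
least 0.9, monotonicity in $\varepsilon$) have comfortable margins while a
full run stays in the minutes range on a laptop core. The optimization
module's own tests use reduced grids; the full 5–43-nt sweep with the
exhaustive feature grid is available but is a compute-budget decision, not a
default.

# Known limitations

* The PseDNC property defaults are a documented choice, not a recovered
  artifact of any particular published model; models trained with different
  property tables are not interchangeable (the archive stores the table).
* Threshold calibration assumes the scanning background resembles the
  training negatives (GC-matched neighbourhoods of positives).
* The optimizer's default grid is geometric in $F$; the stored per-geometry
  optimum can only improve under finer grids.
* `scanTranscripts()` scores every cytosine including heavily N-padded ones
  near transcript ends; their windows carry less information and their
  scores are correspondingly conservative.

# A worked micro-example

```{r example, eval = FALSE}
cfg <- simConfig(nTranscripts = 30, nPositives = 80, effectStrength = 1,
                 minCoverage = 50, seed = 7)
sim <- simulateDataset(cfg)
counts <- simulateBisulfiteCounts(sim$truth, sim$transcripts, cfg)
dataset <- buildTrainingSet(counts, sim$transcripts, seed = 7)
model <- buildEnsembleModel(dataset, upstream = 5, downstream = 5, seed = 7)
model
annotations <- scanTranscripts(model, sim$transcripts)
head(annotations)
contextProportions(annotations[annotations$VH, ], sim$transcripts)
```

The chunk is not evaluated at build time (training takes about a minute);
the README shows a captured run with the numbers it printed.
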
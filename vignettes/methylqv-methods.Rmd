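---
title: "MethylQV: model, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MethylQV: model, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

MethylQV estimates the methylation level (fraction of methylated
molecules) of CpG sites from basecalled, aligned nanopore reads. This
vignette is the package's own account of the method: the statistical
model, every tunable that matters, what the synthetic validation data
do and do not show, and the design decisions taken where more than one
reasonable choice existed.

## Why basecalls carry a methylation signal

5-methylcytosine changes the ionic current as a DNA strand transits a
nanopore. Basecallers trained predominantly on unmethylated DNA
therefore make systematically different — and systematically less
confident — calls around methylated cytosines: per-base quality values
(QVs) drop, and substitution/deletion errors become more frequent and
more correlated across neighbouring positions. Signal-based callers
exploit the raw current directly; MethylQV instead models the
*footprint* that the signal perturbation leaves in the basecalls, which
survive in every BAM file.

## The feature construction

For a candidate cytosine, the unit of analysis is the rectangular
pileup (`WindowPileup`) of the $n$ reads that fully cover the window of
$2f+1$ reference positions centred on it ($f = 10$ by default, 21
positions). Reads that start or end inside the window are excluded, as
are reads matching the exclusion flag mask (default 4079, the standard
single-end filter dropping unmapped, secondary, supplementary,
duplicate, QC-fail and all pairing-related records) and reads carrying
an `N` inside the window. Deletions occupy their reference positions
with the symbol `D` and a configurable placeholder QV.

Writing $Q_{ij}$ for the QV and $R_{ij}$ for the base of read $j$ at
window position $i$, and $T_i$ for the reference base, the feature
families are:

* **Mean QV** $M_i = \frac1n\sum_j Q_{ij}$ — the first-order footprint:
  methylation depresses QVs near the site.
* **Covariance** $V_{pq} = \frac{1}{n-1}\sum_j (Q_{pj}-M_p)(Q_{qj}-M_q)$
  — how QV fluctuations co-move across positions.
* **Coskewness**
  $S_{pq} = \frac{\sum_j (Q_{pj}-M_p)^2 (Q_{qj}-M_q)}{n\,\sigma_p^2\sigma_q}$
  and **cokurtosis**
  $K_{pq} = \frac{\sum_j (Q_{pj}-M_p)^2 (Q_{qj}-M_q)^2}{n\,\sigma_p^2\sigma_q^2}$
  — third- and fourth-order cross-moments capturing the asymmetric,
  heavy-tailed QV distributions that a mixture of methylated and
  unmethylated molecules produces. $S$ is not symmetric (position $p$
  enters squared); $K$ is.
* **Joint error rates**
  $E_{stpq} = \frac1n\sum_j I(R_{pj}=s)\,I(R_{qj}=t)\,I(T_p\neq s)\,I(T_q\neq t)$
  over symbols $s,t \in \{A,C,G,T,D\}$ — the frequency of simultaneous
  non-reference observations at two positions. The indicators force
  structural zeros wherever $s = T_p$ or $t = T_q$, and the tensor
  satisfies the pair-swap identity $E_{stpq} = E_{tsqp}$.
* **Context code** — each reference base as two bits, high bit first
  (A=00, C=01, G=10, T=11): 42 bits. Sequence context strongly
  modulates both QVs and error rates, so the model must be allowed to
  condition on it.

The families are flattened row-major in the fixed order mean (21),
cov (441), coskew (441), cokurt (441), error (11025), context (42) —
12 411 values. The layout is identified by a version string stored in
both feature tables and trained models; a mismatch is refused rather
than silently misinterpreted.

### Numerical choices in the features

* **Spread divisor.** The standardizing $\sigma_p$ uses the population
  divisor $n$ by default, consistent with the $1/n$ prefactor of $S$
  and $K$ (so the diagonal of $K$ is the classical kurtosis, e.g.
  exactly 1 for a symmetric two-point distribution). `sigmaDdof = 1`
  switches to the sample divisor.
* **Zero spread.** Where $\sigma_p = 0$ or $\sigma_q = 0$ the affected
  $S$/$K$ entries are set to 0 rather than NaN, keeping feature vectors
  finite for constant-QV columns (common at high-confidence positions
  and capped QV scales).
* **Deletion QVs.** Deleted positions carry no basecall quality; they
  are imputed with `deletionQV` (default 0), which marks the absence of
  a call distinctly from any real QV. Whether deleted positions should
  instead be excluded from the moments is not determinable from first
  principles; the imputation keeps the pileup rectangular, which the
  formulas require, and the constant is configurable.
* **QV units.** Raw Phred integers from the BAM, no conversion to error
  probabilities — the moments are computed on the scale the basecaller
  emits.
* **Strand pooling.** All reads covering the window contribute
  regardless of orientation; the formulas index reads only by $j$.
* **Window edges.** Loci whose window crosses a contig boundary or
  contains a non-ACGT reference base are skipped and counted, not
  errored: they cannot produce a well-formed feature vector.

## Labels, transform and model

Training labels are per-strand CpG methylation levels from an extended
bedMethyl table (as produced by per-locus modification callers):
score in column 5, coverage in column 10, methylation percent in
column 11. Loci with coverage below 10× or score below 800 are removed
before training — low-coverage or low-confidence labels would teach the
model noise.

Levels $y \in [0,1]$ are logit-transformed before regression. The
default is the epsilon-logit (`mode = "clip"`): clip $y$ into
$[\alpha, 1-\alpha]$ with $\alpha = 10^{-3}$, then
$y' = \log y - \log(1-y)$. A `"literal"` mode implements the piecewise
alternative that maps $y=0 \mapsto -\alpha$ and $y=1 \mapsto +\alpha$
directly; it is retained for fidelity but not default, because it sends
the two boundary labels to *interior* values (logit$^{-1}(\pm10^{-3})
\approx 0.5$), breaking the monotonicity of the label map — fully
methylated loci would be indistinguishable from half-methylated ones on
the transformed scale. The transform mode and $\alpha$ are recorded in
the model metadata.

The regressor is a gradient-boosted tree ensemble (xgboost) with a
squared-error objective on $y'$ — the objective is a package choice, as
boosting admits several; squared error matches the continuous,
roughly homoscedastic transformed labels. Default hyperparameters: eta
0.1, 1500 rounds, max depth 8, all overridable. Training takes an
explicit seed and thread count (tests pin one thread), both recorded,
so model dumps are byte-reproducible. Predictions are mapped back
through the sigmoid and clamped to $[0,1]$; the back-transform is a
package choice, the natural inverse of the clip-mode transform.

Forward and reverse strand records of one CpG site (a `+` cytosine at
$i$ paired with a `-` cytosine at $i+1$) are averaged into a single
site-level record at the forward coordinate, with depths summed;
records violating the CpG geometry pass through unpaired.

Models persist as a directory of two text files: the booster's portable
JSON dump and a JSON metadata sidecar (layout version, flank,
transform, hyperparameters, feature mask, provenance tag naming the
basecaller/flowcell the labels came from). A model trained for one
basecaller/flowcell combination should not be applied to another — the
QV and error patterns differ — which is why the provenance travels with
the ensemble.

### Feature masks

`trainModel(..., featureMask = c("mean", "error"))` restricts training
to named segments, supporting ablation studies of the relative
information content of the families. On the package's own synthetic
data the mean-QV family alone is nearly as informative as the full set
— unsurprising, since the simulator's dominant injected effect is a QV
shift — so the ablation machinery is validated by checking that the
all-features model stays within 0.02 PCC of the best single family, not
by asserting a particular ordering.

## Region aggregation

Two trimming rules summarize site-level methylation over regions:

* **Range trim** (CpG-island rule): keep values inside
  $[\mathrm{median} - v, \mathrm{median} + v]$ where $v$ is the sample
  variance, and average them. "Median ± variance" mixes units, and with
  fraction-valued data the variance band is narrow; a flag switches the
  half-width to the standard deviation for users who prefer
  commensurate units. Degenerate case: with an even count the
  interpolated median plus a narrow band can exclude *every* data
  point; the estimator then falls back to the value(s) nearest the
  median, so it is total and always retains at least one value.
* **Tail trim** (imprinting-control-region rule): sort, drop
  $\lfloor 0.05\,n \rfloor$ values from each end, report mean and
  sample variance of the remainder. With $n < 20$ nothing is dropped.

Region membership is by the C position of the strand-averaged record,
half-open on 0-based coordinates, matching the BED convention of the
inputs. Region-set intersection (e.g. H3K4me3 peaks ∩
DNase-hypersensitive sites) delegates to `GenomicRanges`, cross-checked
in the test suite against a per-base membership oracle.

## The synthetic validation data

`simulateDataset()` generates everything the pipeline consumes: a
uniform-random reference with CpG dinucleotides planted at sites at
least 25 bp apart and 30 bp from contig ends; per-site true levels from
a Beta prior; and single-end, forward-strand, primary-aligned reads
spanning each window, whose per-read methylation state is
Bernoulli(true level). Methylated reads receive an additive QV shift
and additive substitution/deletion probabilities, per window offset
(deletion sampled before substitution at each base; QVs drawn from a
discretized normal truncated to [1, 50]; CIGARs carry real `D` runs so
the BAM parsing path is exercised end to end). The loci table records
the *realized* methylated-read fraction — the label a per-locus caller
would estimate — rather than the latent true level.

Defaults encode the package's validation study: 400 sites, 30×
coverage, Beta(0.3, 0.3) prior (most loci near 0 or 1, as in real
methylomes), QV shift −6 at offsets −2..+2, substitution +0.05 and
deletion +0.03 at the site itself. The unstated baselines are chosen
once as field-realistic: QV mean 20, sd 6 (typical basecalled nanopore
QV scale) over 5% substitution / 2% deletion baseline error. Validation
trains on a random 300 sites with 200 boosting rounds and scores the
100 held-out sites; the test suite requires a held-out Pearson
correlation of at least 0.8 between true and predicted levels, and
`scripts/acceptance.R` recomputes the same quantities from scratch at
runtime.

What the simulator does *not* emulate — and what passing tests
therefore do not show about real data: homopolymer-dependent and
context-dependent error structure, read-length and coverage
heterogeneity, reference bias, mapping artefacts, strand asymmetries,
hemimethylation, and the far weaker and more diffuse effect sizes of
real 5mC on basecall QVs. The simulation demonstrates that the
estimator recovers a methylation signal *of the assumed form* from BAM
input; accuracy on real flowcell/basecaller combinations must be
established by training and evaluating on matched real data, for which
the whole-genome correlations against signal-based callers and
bisulfite sequencing reported for this class of method (per-CpG ~0.9,
region-level ~0.97–0.99) are the reference point. Reproducing those
numbers requires 20–30× human whole-genome datasets and is outside the
scope of this package's self-validation.

## Problem sizes and budgets

The shipped validation uses 400 simulated sites at 30× (feature
extraction ~30 s, each 200-round model fit ~15–45 s on one thread);
unit tests run on 60-site simulations and flank-1 feature layouts (261
columns) where the full 12 411-column geometry is not the point. These
sizes were chosen so the whole suite exercises every pipeline stage,
including the 100-pileup brute-force oracle comparison, in a few
minutes on a single CPU.

## Known limitations

* No per-read (single-molecule) calls: the model regresses the
  site-level methylated fraction.
* CpG/5mC only as shipped; the framework is modification-agnostic but
  untrained for 5hmC or non-CpG contexts.
* No pretrained models for real basecaller/flowcell combinations are
  bundled; users train on their own matched data via the CLI.
* Insertions between window positions are ignored by design; the
  feature geometry is anchored to reference positions.
* The default flag mask 4079 excludes all paired-end records —
  deliberate for single-end nanopore data, configurable otherwise.
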
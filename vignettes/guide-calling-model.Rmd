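---
title: "The guide-calling model: mixture, extraction and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The guide-calling model: mixture, extraction and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model and
its assumptions, the tunable parameters and why their defaults are what
they are, the numerical choices, what the synthetic-data generator does
and does not emulate, and the known limitations.

## The counting problem

A direct-capture CRISPR screen read out in droplets yields, per cell and
per guide, a UMI count: the number of distinct guide cDNA molecules
captured. Two processes generate these counts. Cells that received the
guide's vector transcribe it highly, giving large counts. Every other
cell can still show small counts, because free guide RNA released during
nuclei preparation ("ambient" RNA) is present in every droplet, and
because PCR and sequencing occasionally relocate a molecule. Calling
which cells truly express which guides is therefore a per-guide
two-population classification problem with a heavily zero-inflated
background.

## The mixture model

For a fixed guide, counts across cells are modelled as

$$x \sim (1-\pi)\,\mathrm{ZINB}(w_0, \mu_{lo}, r_{lo})
        + \pi\,\mathrm{NB}(\mu_{hi}, r_{hi}),$$

with the negative binomial in mean/size form,
$P(x) = \frac{\Gamma(x+r)}{\Gamma(r)\,x!}
\left(\frac{r}{r+\mu}\right)^r \left(\frac{\mu}{r+\mu}\right)^x$, and
$\mathrm{ZINB}(x) = w_0\,\mathbf{1}[x=0] + (1-w_0)\,\mathrm{NB}(x)$.

* $\pi \in (0,1)$ — fraction of cells expressing the guide. At MOI 0.1
  with 26 vectors, true per-guide values are of order $10^{-3}$–$10^{-2}$;
  nothing in the fit assumes a lower bound.
* $w_0 \in [0,1)$ — structural-zero weight of the background: droplets
  that captured no ambient molecule of this guide at all.
* $\mu_{lo}, r_{lo}$ — ambient NB mean and size (counts; typically
  $\mu_{lo} < 1$).
* $\mu_{hi}, r_{hi}$ — expressing NB mean and size (counts; tens to
  hundreds of UMIs).

The two NB components are mutually exchangeable unless constrained; we
keep the model identifiable by requiring $\mu_{hi} > \mu_{lo}$, which is
also the scientific meaning of "expressing". The mean/size
parameterization was chosen precisely because this constraint is a plain
inequality between two parameters.

Zeros are observations, not missing data: the model is fitted over every
cell in the supplied cell list, and the ZINB exists to absorb the zero
mass. Fitting is per protospacer, not per vector; pooling the two
protospacers of a vector would hide capture-efficiency differences
between them, and the per-cell assignment step re-joins them anyway.

## Fitting: EM with a quasi-Newton polish

Maximum likelihood uses EM over three expanded latent components —
structural zero (weight $(1-\pi)w_0$), background NB
($(1-\pi)(1-w_0)$), expressing NB ($\pi$):

* **E-step** in the log domain (log-sum-exp throughout).
* **M-step**: weights become responsibility means; each NB is refitted by
  a weighted MLE in which $\mu$ is the weighted mean and $r$ solves the
  weighted digamma score equation by bisection on $\log r$ over
  $[-10, 10]$. Underdispersed weighted samples (variance $\le$ mean) pin
  $r$ at $e^{10}$, the Poisson-like ceiling; if the score has no root in
  the bracket, the bracket end with the higher likelihood is taken.
* **Constraint enforcement** by swap-and-relabel: if an M-step leaves
  $\mu_{hi} \le \mu_{lo}$, the two NB components exchange roles. This is
  a relabelling of an exchangeable pair, so the observed-data likelihood
  is untouched and EM monotonicity survives.
* **Initialization** is deterministic: the counts are split at the 0.80,
  0.85, 0.90 quantiles (one initialization each); moments of the
  lower/upper parts seed the two NBs, the upper-part mass seeds $\pi$,
  and $w_0$ starts at the excess of observed zeros over what the
  background NB alone would produce (floored at 0.1). The best final
  likelihood wins. A `seed` argument is accepted and recorded for
  provenance, but the default fit consumes no randomness.
* **Polish**: EM converges slowly along the ridge where $w_0$ trades off
  against a low-dispersion background NB ($r_{lo} \to 0$ also
  manufactures zeros). After EM, a BFGS step over an unconstrained
  reparameterization — logits for $\pi, w_0$, logs for
  $\mu_{lo}, r_{lo}, r_{hi}$, and the gap form
  $\mu_{hi} = \mu_{lo} + e^{u}$ for the constraint — is *accepted only if
  it improves the likelihood*, so the recorded likelihood trace is
  non-decreasing end to end.

All E/M computations run on the tabulated counts (unique value,
multiplicity): responsibilities depend on a cell only through its count,
so this is an exact reformulation that makes the per-iteration cost
independent of the number of cells.

### Degenerate guides

Two rules route a guide to a count-threshold fallback instead of a
mixture call:

1. **Too little signal**: fewer than `min_positive = 5` nonzero cells.
2. **No evidence of an expressing component**: the fitted 6-parameter
   mixture must beat the best single-ZINB fit (3 parameters) by a
   BIC-style margin, $2\,\Delta\ell > 3\log n$. Without this rule, a
   guide whose vector no cell received — a pure ambient column — gets a
   spurious "expressing" component fitted to the upper tail of the
   background, and every cell with 2–3 ambient molecules would be called
   positive. Genuine but sparse guides (a handful of expressing cells at
   $\mu_{hi} \approx 100$) clear the margin comfortably because each
   expressing cell contributes tens of log-likelihood units.

Fallback guides call `expressed = (count >= 3)` and report the posterior
as `NA`. The threshold of 3 sits above the ambient regime
($\mu_{lo} < 1$) and below any plausible expressing count.

### Calling

$p(x)$ is the posterior of the expressing component, computed in the log
domain, and a cell is called expressing iff $p > 1/2$ **strictly** — a
posterior of exactly one half is not a call. With equal dispersions and
no zero inflation the likelihood ratio is monotone in $x$, so calls are
an interval $x \ge x^\*$; with unequal dispersions the posterior need not
be monotone and is evaluated pointwise rather than thresholded on counts.

## Assignment

Per cell, the called guide set maps to `unassigned` (empty),
`singlet_1ps` (one guide), `singlet_2ps` ($\ge 2$ guides, one target
gene), or `doublet` ($\ge 2$ targets). Congruence is judged on the
library's *target* column, not the vector column: two protospacers
against the same gene from different vectors are congruent, matching the
biological intent (the perturbation is the gene). Non-targeting controls
get one target label per NT vector in the shipped example library, so two
different NT vectors in one cell read as a doublet; users who prefer NT
vectors to be mutually congruent can give them a shared label.

Because "assigned" is genuinely ambiguous when doublets are counted,
summaries report both conventions — any called guide, and congruent
singlets only. The median guide-UMI statistic is computed over cells with
at least one guide UMI (the rank-plot convention); a switch extends it to
all cells.

## Extraction design

* The protospacer and the CS1 anchor are searched independently anywhere
  in the read ("the read contains both"), each by a sliding Hamming scan
  with at most `d_max = 1` mismatches and no indels; `N` never matches.
  Matching positions are reported 1-based, the R convention.
* When several protospacers match, the fewest mismatches wins and exact
  ties discard the read — at library distances (random 20-mers are
  $\ge 10$ apart) a tie means the read is uninterpretable, not that
  either guide is plausible.
* Cell barcodes correct to the whitelist by exact match, else a *unique*
  Hamming-1 neighbour; ambiguous or distant barcodes drop the read
  rather than risking cross-cell bleed.
* UMI collapse defaults to exact distinct strings; the `directional`
  mode merges Hamming-1 neighbours into the higher-count UMI (ties: the
  lexicographically smaller absorbs) and is the right choice whenever
  sequencing depth exceeds one read per molecule.
* The default layout (16 bp barcode at offset 0 of stream 1; 12 bp UMI at
  offset 0 of stream 2, which is also the protospacer-bearing stream) is
  fully configurable — which stream carries which element, offsets,
  lengths, anchor, `d_max`, and barcode reverse-complementing — because
  capture chemistry and sequencing recipes vary.

## The synthetic-data generator

`simulate_counts()` draws, per cell, $k \sim \mathrm{Poisson}(\mu_{MOI})$
vectors without replacement; each received vector adds
$\mathrm{NB}(\mu_{hi}, r_{hi})$ counts to each of its protospacers, and
every (cell, guide) pair receives $\mathrm{ZINB}(w_0, \mu_{lo}, r_{lo})$
ambient counts on top. `simulate_fastq()` expands each molecule into
$1 + \mathrm{Geometric}(1/\rho)$ reads and assembles reads per the
layout, with i.i.d. per-base substitutions at rate $\varepsilon$.

Defaults — MOI 0.1, $\mu_{hi} = 100$, $r_{hi} = 5$, $w_0 = 0.7$,
$\mu_{lo} = 0.5$, $r_{lo} = 1$, $\rho = 4$, $\varepsilon = 0.005$ — are
the screen-like regime used across the package's validation: a low-MOI
pooled screen with a clearly separated expressing component, around a
hundred UMIs per expressing guide, sparse ambient background, a few reads
of PCR duplication per molecule, and sub-percent sequencing error.

What the generator deliberately does **not** emulate:

* Ambient counts are i.i.d. across guides, not proportional to each
  guide's abundance in the pool. Real ambient contamination is
  pool-proportional; a per-guide calling model is blind to the
  difference, but pool-level diagnostics would not be.
* Cell doublets (two nuclei in one droplet) are represented only through
  multi-vector uptake; barcode-sharing artifacts, chimeric PCR and index
  hopping are absent.
* Reads carry no quality information (matching is quality-blind anyway),
  and errors are substitution-only — as is the Hamming matcher.

Consequently, passing tests demonstrate correctness of the algorithms
under the model's own assumptions, and calibration on data *shaped* like
a real screen; they do not certify performance on any particular real
dataset, whose ambient structure, saturation and error profile must be
expected to differ.

## Validation choices and problem sizes

The test suite and `scripts/acceptance.R` compute: mixture parameter
recovery and likelihood properties on 20 replicate cohorts of 20,000
counts at the default regime; pmf normalization over a
$\mu \times r \times w_0$ grid by truncated summation (support truncated
at $\mu + 50\sqrt{\mu + \mu^2/r}$); posterior agreement with a naive
linear-domain ratio on $x = 0..300$ at 50 random parameter sets;
extraction fidelity on an error-free ~5,000-read cohort (exact
reproduction required) and a 200-cell, ~20,000-read cohort at
$\varepsilon = 0.01$ (fraction of matrix entries exactly recovered — the
larger cohort makes this fraction a stable quantity; the irreducible
misses are UMIs whose reads all carry $\ge 2$ substitutions in the
12-mer, which no Hamming-1 collapse can repair); and end-to-end category
recovery on a 5,000-cell cohort. These sizes were chosen so each quantity
is measured with small sampling noise while the whole suite stays quick
to run.

## Known limitations

* The per-guide model ignores information shared across guides (a cell's
  total ambient load, vector structure); a hierarchical model could
  borrow strength for very sparse guides.
* Hamming-only matching misses indel-bearing reads; at guide-library
  distances this costs sensitivity, never specificity.
* The BIC degeneracy margin is a model-selection heuristic; guides whose
  true expressing population is both tiny and weak
  ($\pi n \lesssim 5$ cells or $\mu_{hi}$ near the ambient range) fall
  back to the count rule by design.
* The directional UMI collapse resolves ties lexicographically to stay
  deterministic; this is a convention, not an error model.
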
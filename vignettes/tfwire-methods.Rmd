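---
title: "tfwire: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tfwire: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfwire)
```

## Overview

`tfwire` identifies transcription factors (TFs) whose co-expression wiring
changes between two biological conditions, and reconstructs one
co-expression network per condition. The pipeline has four stages — data
adjustment, a standardized differential-expression contrast, Regulatory
Impact Factor (RIF) scoring, and the Partial Correlation and Information
Theory (PCIT) trio filter — each exposed as a plain function so every stage
can be run, inspected and tested on its own.

## Data adjustment

Raw counts are scaled per column to transcripts-per-million,
$\mathrm{TPM}_{gs} = 10^6\, x_{gs} / \sum_g x_{gs}$. This is deliberately a
pure library-size scaling with **no transcript-length correction**: the
statistic downstream is a correlation between genes across samples, which
is invariant to any per-gene constant factor, so length correction would
change nothing that matters here while requiring an annotation input.

The gene filter computes two *global* scalars — the mean of all nonzero
entries, and the mean of all entries — and keeps a gene iff its own mean
expression strictly exceeds half of **both**. Two readings of "half of the
means" are possible (global vs. per-gene); the global reading is
implemented because the thresholds are then auditable as two numbers, which
the filter report records in its header. Ties at the boundary are dropped
(the rule is "above half"). A per-gene variant would be a one-line change
but is not offered until a use case demands it; silently switching rules is
worse than a strict default.

Finally values are mapped to $\log_2(x + 1)$. The map is strictly
increasing, so within-sample rankings survive, and $0 \mapsto 0$ keeps
sparsity visible.

Pre-normalized input (TPM/FPKM) skips the scaling and log steps; only the
filter is applied.

## The differential-expression contrast

For gene $g$, $s_g$ is the difference of condition means on the normalized
scale, and

$$\mathrm{diff}_g = \frac{s_g - \overline{s}}{\sqrt{\widehat{\mathrm{var}}(s)}}$$

standardizes the $s$ vector **across genes** (the variance is across genes,
not samples: the contrast asks "how unusual is this gene's shift relative
to all genes' shifts"). The sample ($n-1$) variance is used — the
conventional choice for a z-standardization; with hundreds of genes the
$n$-vs-$n-1$ distinction is far below any decision boundary. By
construction the scores have mean 0 and SD 1, so a cutoff of 1.96 (default)
is a nominal two-tailed 5% screen and 2.57 a 1% screen. The cutoff is
strict: a score exactly at the boundary is *not* DE, which keeps the
classification deterministic under exact ties. There are no p-values by
design — the method is a screen, not a test with error control.

Swapping the reference and alternate labels negates every score exactly;
this antisymmetry is asserted in the tests.

## RIF scoring

For each condition $c$, the Pearson correlation $r^{(c)}_{ij}$ between
every TF $i$ and every DE gene $j$ is computed over that condition's
samples (at least 3 per condition). With $a_j$ the DE gene's overall mean,
$e^{(c)}_j$ its condition mean and $\mathrm{diff}_j$ its contrast score:

$$\mathrm{RIF1}_i = \frac{1}{n_{de}}\sum_j a_j\,\mathrm{diff}_j\,
  \bigl(r^{(1)}_{ij} - r^{(2)}_{ij}\bigr)^2,\qquad
  \mathrm{RIF2}_i = \frac{1}{n_{de}}\sum_j
  \bigl(e^{(1)}_j r^{(1)}_{ij}\bigr)^2 - \bigl(e^{(2)}_j r^{(2)}_{ij}\bigr)^2.$$

RIF1 rewards TFs whose wiring to abundant, strongly DE genes changes most;
RIF2 measures the change in the TF's squared ability to predict DE-gene
abundance. Design choices worth stating:

* The phenotype impact factor uses the **signed** contrast
  ($a_j \cdot \mathrm{diff}_j$), not its absolute value: the direction of
  regulation is part of the weighting, and under a condition swap both raw
  scores then negate exactly — a clean, testable symmetry.
* DE genes that are themselves catalog TFs are kept on the TF side only; a
  regulator is scored, not scored against.
* Zero-variance profiles within a condition get correlation 0 with a
  warning rather than aborting: one flat gene should not kill a
  whole-matrix run, and the events are enumerable from the log.
* Both raw and z-standardized ($n-1$ SD) scores are emitted so the
  formulas are auditable; significance is $|\mathrm{RIF}| > 1.96$ on the
  standardized scale, the two-tailed 5% normal point. Standardizing first
  is an interpretation (the criterion is stated for the scores without a
  scale); it is the only reading under which 1.96 has meaning.
* TFs named in the catalog but absent from the matrix are reported, never
  silently dropped.

## PCIT

For every unordered trio $\{x, y, z\}$ of the node set, the three
first-order partial correlations (e.g.
$r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$)
and the trio tolerance

$$\varepsilon = \tfrac{1}{3}\left(\frac{r_{xy.z}}{r_{xy}} +
  \frac{r_{xz.y}}{r_{xz}} + \frac{r_{yz.x}}{r_{yz}}\right)$$

are computed, and edge $(x,y)$ is discarded when
$|r_{xy}| \le |\varepsilon\, r_{xz}|$ **and**
$|r_{xy}| \le |\varepsilon\, r_{yz}|$ (the other two edges symmetrically).
An edge discarded in *any* trio is non-significant: significance means
surviving every conditioning context. Numerical corner cases are handled
explicitly:

* A trio containing an exactly-zero direct correlation has an undefined
  tolerance ratio; such trios are non-informative and issue no discards
  (they are counted and reported).
* Off-diagonal $|r| = 1$ entries are clamped to $\pm(1 - 10^{-12})$ with a
  warning so the partial-correlation denominators never vanish.
* With fewer than 3 nodes no trio exists and all pairs stay significant.

The published form of the discard rule contains a self-comparison
($|r_{xz}| \le |\varepsilon r_{xz}|$) that is internally inconsistent with
its own prose; the corrected rule above is the default and the literal
variant is kept behind `eq7_variant = "as_printed"` purely for audit.

One behavior deserves emphasis because it surprises people: $\varepsilon$
is a *mean of ratios*, so a trio pairing one very weak edge with two strong
ones can have $|\varepsilon| \gg 1$, and then **all three** edges of that
trio fail the test — including the strong ones. That is what the equations
say, the compiled loop and the independently written naive oracle agree on
it edge-for-edge, and the package does not second-guess it.

The trio loop is $O(n^3)$ time, $O(n^2)$ memory, implemented in C++
(≈ 56 s for $n = 2{,}000$ nodes on one CPU). The pipeline keeps $n$ small
by default: the PCIT node universe is DE genes ∪ RIF-significant TFs
(`pcit_node_policy = "de_plus_sig_tfs"`), with DE genes ∪ all TFs as the
configurable alternative.

## Networks and the TFs-HRi table

Significant pairs become undirected, correlation-weighted edges — one
network per condition. "Frequency of appearance" of a TF is interpreted as
its **degree** in the condition network, which is what a count of a TF's
occurrences in an edge list is. The TFs-HRi table joins the RIF scores of
the significant TFs (optionally all TFs) with their two degrees and
`freq_diff = freq_ref - freq_alt`, sorted by `freq_diff` descending: a
large positive value marks a TF wired mainly in the reference condition. A
TF absent from a network simply has degree 0. The average local clustering
coefficient counts nodes of degree < 2 as 0 (the "no neighbor pair"
convention), so a star scores 0 and a clique 1; the implementation is
cross-checked against igraph's in the tests.

## The synthetic world

`sim_counts()` draws a latent log2 expression for every gene: baseline
$\log_2(\texttt{base\_mean})$ plus i.i.d. Gaussian noise of SD
`noise_sd`, and for the planted module and its TF an added shared-factor
term with loading $\lambda_c = \texttt{noise\_sd}\sqrt{\rho_c/(1-\rho_c)}$,
which makes every pairwise correlation among them $\rho_c$ in condition
$c$ (a negative $\rho$ flips the TF's loading only). Module genes get a
`de_effect` log2 shift in condition 2. Counts are then negative-binomial
with mean $2^{\text{latent}}$ and size `nb_dispersion`
(variance $\mu + \mu^2/\text{size}$).

Default world: 300 genes, 20 TFs, 50 samples/condition,
$\rho = (0.8, 0)$, module 20, `de_effect = 2`. The two free noise
parameters were fixed once, before any acceptance measurement, at values a
bulk-RNA-seq analyst would call realistic: `noise_sd = 1` (a 2-fold
biological SD across samples on the log2 scale) and `nb_dispersion = 50`
with `base_mean = 100` (count-layer CV ≈ 0.17, i.e. technical noise well
below biological). With these, the count-sampling layer attenuates the
planted 0.8 correlation to ≈ 0.79 on the log scale, comfortably inside the
±0.1 recovery band asserted in tests — had the NB layer been made noisier
than the biological layer the stated world itself would be incoherent.
`base_mean` is count-scale in `sim_counts()` and log2-scale in
`sim_norm()` (which emits the latent values directly); the two generators
share a spec, so the field is interpreted per output scale and documented
as such. With `noise_sd = 0`, `sim_norm()` uses a unit-scale loading (the
$\rho$-matching loading is proportional to `noise_sd`), making module rows
exact affine images of the factor.

What the generator deliberately does **not** emulate: library-size
variation between samples, gene-length effects, count overdispersion
heterogeneity across genes, correlated null structure, batch effects, or
any empirical distribution from real cohorts. A green recovery test
therefore establishes that the pipeline's statistics recover the planted
structure under a clean latent-factor world — not that they would rank
regulators correctly in a confounded real data set.

Correlation-recovery assertions summarize the TF-module correlation by its
**mean** over the 20 module genes: a single correlation at $n = 200$ has
sampling SD ≈ 0.07, so a max-based ±0.15 check on 20 draws would fail a
large fraction of honest seeds by chance alone.

All randomness flows through one seed stored in the spec; generation
restores the caller's RNG state, and the same spec is bit-reproducible.

## Pipeline, determinism, degenerate inputs

`run_analysis()` executes the stages strictly in order (no stage reads a
later stage's output), writes each table in stage order, and echoes the
full configuration, package version, seed and all dimensions into
`manifest.json`. Nothing timestamped is written, so identical config +
seed gives byte-identical artifacts — asserted at the file level in the
acceptance suite. Stage errors abort with the stage name in the message
and a nonzero exit status from the CLI.

Degenerate inputs are errors where silence would mislead: all-zero samples
(TPM undefined), an empty post-filter gene set, identical conditions
(zero-variance contrast), a single TF (standardization undefined), fewer
than 3 samples per condition (no correlation degrees of freedom). One
deliberate exception: if fewer than two nodes qualify for PCIT (e.g. a
very strict DE cutoff on a small matrix), the pipeline emits structurally
valid empty networks rather than failing a run whose upstream tables are
fine.

## Known limitations

* The DE screen has no error control; cutoffs are nominal normal points.
* RIF formulas follow the original method's published description; the
  source summarizing them prints only the significance criterion, so both
  raw and standardized scores are emitted for auditability.
* PCIT's all-trio survival rule makes edge significance sensitive to the
  node universe: adding nodes can only remove edges, never add them.
* The average-ratio tolerance can exceed 1 in mixed-strength trios and
  discard strong edges (see above); this is inherent to the method, not a
  bug.
* No enrichment, diffusion, or plotting layers: tables, SIF and GraphML
  out; downstream tools take it from there.
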
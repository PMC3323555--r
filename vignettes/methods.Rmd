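---
title: "Methods: eQTL mapping and probe-level artifact correction in RI panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL mapping and probe-level artifact correction in RI panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bxdeqtl)
```

## The analysis problem

In a recombinant-inbred (RI) panel each strain is a fixed homozygous
mosaic of two parental genomes (here labelled B and D after the BXD
family's C57BL/6J and DBA/2J founders), so every strain can be measured
repeatedly and genotypes are reused across experiments. Transcript
abundance measured across such a panel is a quantitative trait: loci whose
allelic state covaries with a transcript's expression are expression QTLs
(eQTLs), *cis* when they sit within or near the gene itself and *trans*
otherwise. The package implements the full chain from probe-level
microarray intensities to prioritized candidate regulators, together with
a generative simulator used to validate every estimator on panels with
known architecture.

## Statistical model

### Single-marker scan

For a strain-mean trait $y$ and marker genotype $g \in \{-1, 0, +1\}$
(B, H, D; unknowns dropped pairwise) the scan fits $y = \mu + a g$ by
least squares at each marker and reports

$$\mathrm{LRS} = n \ln \frac{\mathrm{RSS}_0}{\mathrm{RSS}_1},$$

the Gaussian maximum-likelihood likelihood-ratio statistic, where
$\mathrm{RSS}_0$ is the residual sum of squares about the mean and $n$ the
informative strain count. This form satisfies the exact identity
$\mathrm{LRS} = -n\ln(1-r^2)$ with $r$ the trait–marker Pearson
correlation, and converts to a LOD score as $\mathrm{LOD} =
\mathrm{LRS}/4.61$. Both identities are enforced by tests against an
independent likelihood oracle (explicit ML fits scored with `dnorm`).
The additive effect is reported as half the difference between the D- and
B-class means, so its sign names the high allele. RI strains are
essentially homozygous; residual heterozygotes are coded 0 and no
dominance term is fitted. Marker regression (rather than interval mapping
at pseudo-markers) is the engine, and is recorded in output metadata.

### Permutation thresholds

Genome-wide significance is calibrated by permuting the trait over strains
(default `n_perm = 1000`, minimum 100) and taking quantiles of the null
distribution of the genome-wide maximum LRS: the 95th percentile is the
*significant* threshold and the 37th percentile (genome-wide p = 0.63,
the conventional "one false positive per scan" level) the *suggestive*
threshold. Thresholds are seed-reproducible; the suggestive quantile
choice follows the standard RI-mapping convention since only the 95th is
universally defined.

### cis/trans rule and peaks

The scan peak is the maximum-LRS marker, ties broken toward the lowest
genomic coordinate so calls are deterministic. A peak is only reported at
or above the suggestive threshold. It is classified *cis* when it lies on
the cognate gene's chromosome and the distance from the peak position to
the gene *span* (not its midpoint) is at most 10 Mb, *trans* otherwise —
including any peak on another chromosome. The window is configurable
(`cis_window_mb`), and reporting gates default to LRS > 15, the
conventional genome-wide significance landmark for these panels.

### Broad-sense heritability

$h^2 = \mathrm{Var}(\text{strain means}) / \mathrm{Var}(\text{all
measurements})$, both population variances, clipped to $[0,1]$. With $r$
replicates per strain and genetic variance $G$ this estimator's
population value is $(G + \sigma_e^2/r)/(G + \sigma_e^2)$; it equals the
classical variance ratio only as $r \to \infty$, and with a single
replicate it is identically 1. The simulator plants heritability in the
estimator's own convention (below), which keeps recovery tests coherent.

### Probe filtering and PC1 reconstruction

Probes overlapping a B-vs-D sequence variant are removed outright; a
probe set losing all probes is flagged unusable rather than summarized.
Surviving probes of a set are centered and unit-scaled across strains and
the first principal component's strain scores become the probe-set
profile (correlation-matrix PCA; whether to standardize probes first was
an open choice — standardizing makes the summary robust to probe-specific
scale and is recorded in output metadata). PC1 is sign-oriented to
correlate positively with the mean probe profile; an unoriented PC1 would
randomize downstream allele-direction calls. The scores are re-expressed
as `mean expression + score × mean probe SD` so summaries stay on the
log2 scale. A single surviving probe passes through unchanged with
variance fraction 1; a zero-variance set degenerates to a constant
profile with a flag.

Probe sets below a mean-expression floor (default 8 on the log2 scale,
typical for 3′-biased arrays; 10 is appropriate for exon-style platforms)
are excluded from mapping and network stages; the floor is
config-overridable.

### Presentation conventions

`standardize_2z8()` maps every row to mean 8, SD 2 using the *population*
SD, which makes "SD of 2" exact per row and the operation idempotent to
1e−9. `fold_change()` is $2^{\max - \min}$ of the log2 strain means.
Constant rows standardize to 8 with a warning.

### Coexpression and candidates

Networks keep edges with $|r| \ge 0.3$, binned half-open:
bold $[0.7, 1]$, normal $[0.5, 0.7)$, dashed $[0.3, 0.5)$ — which side of
each boundary is closed was unspecified in the field convention we
follow, so the half-open choice is documented here and asserted in tests.
Probe sets of one gene are collapsed when pairwise $r > 0.8$: pairs are
averaged, larger groups take the sign-oriented PC1. Because the rule is
stated pairwise, groups are formed by single linkage (the minimal
consistent closure); groups containing sub-threshold pairs are flagged
`mixed`. Module eigengenes are the sign-oriented PC1 of standardized
member profiles and feed directly into the scan as composite traits.

Candidates inside a trans interval (default half-width 5 Mb around the
peak, matching the few-Mb regions such analyses name; configurable) pass
the five-criteria screen — cis LRS > 15, $|r| > 0.3$ with the target,
polymorphic, expressed, and optionally supported by an external
expression atlas supplied as a boolean column (atlas imagery itself is
out of scope). Survivors are ranked by first-order *Pearson* partial
correlation controlling the peak-marker genotype code (−1/0/+1, not a
binarized indicator); a rank-based variant was considered and left out as
the field's convention is Pearson on these panels. The formula value is
tested to 1e−12 against the residual-regression identity. Ties rank by
higher $|r|$, then lexicographic symbol. Cross-species support counts
datasets with $|r| \ge 0.3$ and requires at least three human and three
mouse datasets to call consistency.

## The generative model

`simulate_expression_panel()` draws probe-level log2 intensities as

$$y_{pit} = \mu_p + a_{cis} g_i + \textstyle\sum a_{trans} g_i' +
\lambda f_i + u_i + e_{pit} - \delta\,\mathbb{1}[\text{variant probe, D
at probe locus}]$$

with genotypes from a first-order Markov mosaic per chromosome: the
recombinant fraction between adjacent markers is $R = 4r/(1+6r)$
(sib-mated RI map expansion) with $r$ from Haldane's map function on the
cM gap — a closed form the simulator is tested against. Defaults are the
package's reference study conditions, chosen once to mirror a dense BXD
expression experiment at desk scale:

| parameter | default | meaning |
|---|---|---|
| `n_strains` | 70 | RI panel size (real panels run ~67–72 strains) |
| `n_replicates` | 3 | arrays per strain |
| map | 10 chr × 20 markers, 5 Mb / 2.5 cM spacing | desk-scale genome giving significant LRS thresholds in the mid-teens |
| `sigma_g` | 0.2 log2 | polygenic strain SD |
| `sigma_e` | 0.3 log2 | per-probe array noise SD |
| `delta` | 1.0 log2 | artifact depth for variant probes (a free parameter; no quantitative field value exists) |
| `probes_per_set` | 11 | M430-style probe-set design |
| `n_variant_probes` | 3 | flagged probes per affected set (upper end of the 1–3 typically observed) |

The artifact sign is fixed: variant-overlapping probes are designed
against the B reference, so D-carrying strains lose signal. Region-specific
trans effects may carry opposite signs for proximal versus distal 3′ UTR
probe sets of one gene, reproducing the discordant-isoform regulation
pattern; a latent module factor $f = a_m g + \varepsilon$ with per-gene
loadings creates coexpression modules mappable through their eigengene.

**Heritability planting.** When a gene carries an `h2_target`, the total
genetic variance is solved from the estimator's population value:
$G = \sigma_e^2 (h^2 - 1/r)/(1 - h^2)$, attainable only for
$h^2 > 1/r$; the polygenic SD absorbs $G$ minus the fixed-effect
variances. Planting in any other convention would make the estimator's
recovery systematically biased by $\sigma_e^2$-dependent terms, i.e. the
test would measure the convention mismatch rather than the estimator.

**What the simulator does not emulate:** linkage disequilibrium beyond
first-order Markov structure, epistasis, X-dosage, batch effects,
platform-specific intensity distributions, or shared probe sequence
between genes. Recovery results on these panels therefore demonstrate the
estimators' correctness under the stated model, not performance on any
particular real dataset.

## Numerical choices and degenerate inputs

- Positions are decimal megabases throughout; BED input (0-based
  half-open, base pairs) is converted on read.
- U (unknown) genotype calls are preserved by I/O and dropped pairwise in
  scans; they are never imputed. Readers reject rather than coerce:
  unknown calls, non-numeric cells and malformed rows fail with the
  offending line or coordinates named.
- Markers with a single genotype class, fewer than 3 informative strains,
  or a constant trait score LRS 0 with an undefined effect.
- Zero additive effect at a peak reports `B_high` with a `zero_effect`
  flag rather than an arbitrary direction.
- The permutation scan uses the $-n\ln(1-r^2)$ identity on standardized
  matrices for complete data (one BLAS cross-product for all
  permutations) and falls back to the full pairwise-complete scan when
  missing values are present; the two paths are tested against each
  other.

## Study sizes

The packaged simulation studies (`study_type1_error()` and friends, run
by both the test suite and `scripts/acceptance.R`) use 500 null panels of
40 strains for threshold calibration, 100 panels of 60 strains for cis
recovery, artifact removal, regulator ranking and module mapping, and 50
panels for heritability recovery — sizes at which the binomial/mean
sampling error is comfortably below each study's decision band. The
planted cis effect in the recovery study (0.3 log2 units against the
default variance components) represents a strongly cis-regulated
transcript, explaining well over the 40% of strain-mean variance the
recovery claim assumes.

## Interfaces

The package is driven from R: every stage is an exported function and
`run_pipeline()` wires them (simulate → preprocess → heritability → map →
network → candidates) with a flat key = value configuration, `.partial`
staging of outputs, and a provenance record (config hash, seed, package
version, decision tags) sufficient to re-run any stage exactly; with a
fixed config and seed the outputs are byte-identical. No shell entry
point is shipped — `scripts/acceptance.R` is the scripted end-to-end run.

## Known limitations

Single-marker regression cannot separate linked QTLs or estimate
locations between markers; no kinship correction is applied (RI panels
are balanced, but shared ancestry still inflates some long-range
correlations); the five-criteria screen consumes atlas and polymorphism
evidence as annotations rather than computing them; and the cross-species
module definition is consumed as a gene list, not recomputed.
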
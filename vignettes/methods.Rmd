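---
title: "Autosome-substitution linkage analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autosome-substitution linkage analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscalink)
```

## The genetic design

Two parental house fly strains anchor the design: ALHF, a
multi-insecticide-resistant strain whose five autosomes all carry the
resistant ("R") state, and aabys, a susceptible strain carrying one
recessive morphological marker per autosome ("S" state). Five
substitution lines each replace exactly one ALHF autosome with its aabys
counterpart; a line's name lists the autosomes *retained* from ALHF, so
A1234 carries the aabys autosome 5 and A2345 the aabys autosome 1.
`line_designs()` encodes these seven genotypes; `parse_line_name()`
validates and parses arbitrary names; `substituted_autosome()` gives the
line-to-autosome map used throughout (A2345→1, A1345→2, A1245→3,
A1235→4, A1234→5).

The inferential idea: if a gene's expression drops when autosome $a$ is
substituted, a factor required for its up-regulation resides on $a$. The
set of such autosomes is the gene's *linkage set*; its exact-subset class
in the Venn partition describes which autosomes co-regulate it. Lines are
modeled as homozygous for the retained ALHF autosomes (the real lines
were marker-sorted and permethrin-selected to fix them); heterozygosity
and within-autosome recombination are not modeled.

## Expression model of the simulator

Each simulated gene has a baseline $b_g$ (log2 units), a physical
autosome, a factor set $F_g \subseteq \{1..5\}$ and per-factor effects
$\beta_{g,a} > 0$ (log2 units). Under the default **additive** model the
expected log2 expression in a line with genotype $G$ is

$$\mu_g(G) = b_g + \sum_{a \in F_g,\ G[a]=R} \beta_{g,a},$$

multiplicative on the linear scale. The autosome-substitution design
cannot distinguish additive from conjunctive (AND) co-regulation; additive
is the default because the observed single-substitution losses are
partial, not total. An **AND** mode (`model = "and"`), in which any
missing factor collapses expression to baseline, is available for
sensitivity analysis. Consequences of additivity used as test invariants:
no substitution line ever exceeds ALHF, with equality exactly when the
substituted autosome is not a factor; the ALHF:aabys fold-change is
$2^{\sum_a \beta_{g,a}}$.

Measurement layers on top of $\mu_g$:

* **Replicates** (`simulate_replicates()`): linear expression
  $2^{\mu + \varepsilon}$, $\varepsilon \sim N(0, \sigma^2)$ i.i.d. per
  biological replicate — lognormal noise, matching the strictly positive,
  right-skewed scale of relative expression.
* **Counts** (`simulate_counts()`): negative binomial with mean
  proportional to linear expression × gene length, scaled so a sample's
  expected total equals `mean_depth`; variance $\mu + \phi\mu^2$, and
  $\phi = 0$ degenerates to Poisson. The recorded `library_size` is the
  normalisation denominator.
* **Ct values** (`simulate_ct()`): $Ct = c_g - \mu_g(G) + \varepsilon$
  with a constant-Ct reference gene, making the generator the exact
  inverse of the 2^-ΔΔCt computation (amplification efficiency fixed at
  2, as the formula assumes). The reference (β-actin) is simulated
  strictly constant across strains, mirroring the assay's validated
  endogenous control.
* **Bands** (`simulate_bands()`): a band is present iff the line carries
  R at the gene's physical autosome — deterministic by default; a
  `dropout` rate exists (default 0) to probe robustness.

### Default scenario and parameter choices

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 200 | the scale of the qPCR validation panel, ~3x |
| `n_reps` | 3 | triplicate biological replication of the assay |
| `noise_sd` | 0.15 log2 | ~11% CV, typical of well-run qPCR triplicates; the study reports no replicate variance, so this is a modeling choice |
| effects $\beta$ | Uniform(0.8, 1.6) | 1.7–3-fold losses, the bulk of the printed table |
| class priors | observed partition frequencies (21/59 on {2,5}, etc.) | the generator's architecture mix mirrors the study's realized classes |
| `mean_depth` | 1e5 | desk-scale library depth; large enough for the DE screen's power at log2FC 2 |
| `dispersion` | 0.05 | moderate biological NB overdispersion for bulk RNA-Seq |
| `ct_noise_sd` | 0.1 cycles | sub-quarter-cycle technical scatter |

All generators are bitwise reproducible under a fixed seed; seeds are
restored to the caller's RNG state afterwards.

## Quantification and significance

`ddct()` computes per sample $\Delta Ct = \overline{Ct}_{target} -
\overline{Ct}_{ref}$, $\Delta\Delta Ct$ against the calibrator, and
relative expression $2^{-\Delta\Delta Ct}$; the calibrator's value is
exactly 1 by construction, and the statistic is invariant to any constant
added to one sample's target and reference Cts together (the
normalisation property). Replicate-level values — each target replicate
normalised against the sample's mean reference Ct — preserve scatter for
the significance test.

`welch_test()` implements the unequal-variance t-test from summary
statistics ($t = \Delta m / \sqrt{se_1^2 + se_2^2}$,
Welch–Satterthwaite df), so it serves both replicate-level data and the
printed mean ± SE table. Degenerate zero-variance inputs are defined
explicitly: equal means give $p = 1$, unequal means give $p = 0$ with a
`degenerate` flag — the limit that makes the zero-noise pipeline exact.
Significance is two-sided at α = 0.05 per test, with **no**
multiple-testing correction across lines or genes, matching the assay's
per-comparison convention; direction is recorded separately. BH
correction lives only in the DE screen.

Two testing conventions deserve note:

* The suite cross-checks `welch_test()` against `t.test()` on replicate
  data (the reference implementation is the oracle, never the
  implementation) and against the exact two-sample permutation test.
  The permutation comparison uses **five** replicates per group: at
  $n = 3 + 3$ the permutation distribution has only 10 distinct
  relabelings, its smallest two-sided p-value is 0.1, and a 0.05-level
  permutation test can never reject — the comparison is only meaningful
  once the permutation granularity passes the test level.
* Small-$n$ Welch is approximate: under the null at $n = 3$ its
  empirical type-I error sits near 0.03–0.04, inside the accepted
  [0.02, 0.09] band rather than exactly at 0.05.

## Linkage, partition, and the printed table

`call_linkage()` turns per-line significance into linkage sets. For the
packaged 70-gene table the printed asterisks **are** the calls: the
printed SEs are rounded to 1–2 digits, so p-values recomputed from them
are diagnostic only (they reproduce ~82% of the printed flags) and never
override the published calls. `use_printed_flags = FALSE` exposes the
recomputation for diagnostics. Significance in either direction creates a
linkage edge — four protease genes respond to the autosome-4 substitution
with mixed directions elsewhere, and the exact-subset partition places
them in the {3,4,5} and {2,4,5} classes, as the narrative does. Genes
whose assays were withdrawn (printed as dashes) are `no_data` and excluded
from the partition denominator: 59 of 70 genes are called.

`venn_partition()` assigns each called gene to the exact subset of its
linkage set — classes are disjoint and exhaustive by construction, and
`subset_count()` returns 0 for unrealized subsets rather than erroring.
Autosome 4 participates fully in the partition data model.

## Physical mapping and cis/trans

`infer_location()` applies the single-absence rule: the
ALHF-allele-specific primer amplifies only the ALHF allele, so the one
substitution line lacking a band carries the gene's autosome from aabys.
All-present patterns are `unmapped` (no discriminating absence); two or
more absences, tied replicate votes (`merge_band_replicates()`, majority
vote, ties → `NA`), or inconsistent parental rows (ALHF absent, aabys
present) are `ambiguous`. Parental rows only check consistency; they
never map. The worked-example band table is **encoded from the published
mapping statements** (three genes on autosome 5, five on autosome 2), not
from a band-image matrix, which the study never tabulates.

`classify_regulation()` intersects location with linkage: `cis_only`
(linkage = {location}), `trans_only` (location excluded, set non-empty),
`cis_plus_trans` (location plus others), `unlinked` (empty set). "Cis"
is autosome-level coincidence only — the design cannot prove the cis edge
is a regulatory factor rather than the gene's own locus, so
`cis_plus_trans` genes carry a `cis_or_locus` flag.

## The DE screen stand-in

The original screen ran a full RNA-Seq pipeline; reproducing it requires
the archived reads and is out of scope. The package substitutes the
closest desk-scale analogue whose behaviour is verifiable by enumeration:

* `fpkm()` — $10^9 \cdot count / (length \cdot library\_size)$.
* `estimate_common_dispersion()` — method of moments after scaling to the
  geometric-mean depth: median over genes of
  $\max(0, (s^2 - \bar m)/\bar m^2)$ from within-group moments. It
  recovers simulated $\phi$ to within a factor of ~2 and returns exactly
  0 for constant counts; mild underestimation at $n = 2$ per group is
  expected and absorbed by the FDR margin.
* `nb_exact_test()` — conditional on a gene's total after library
  equalization (total-count scaling to the geometric mean; TMM is not
  implemented, a documented difference). Group sums of NB counts are NB
  with shape $n/\phi$, so the conditional split follows a negative
  hypergeometric law free of the mean; $\phi = 0$ reduces exactly to the
  conditional binomial (exact Poisson) test. Two-sided p-values sum all
  splits with probability ≤ the observed one; ties are included in the
  tail (conservative), with a $1 + 10^{-12}$ relative guard against
  floating-point ties. Library equalization rounds scaled counts to
  integers before conditioning.
* `bh_fdr()` — the Benjamini–Hochberg step-up rule, cross-checked against
  `p.adjust(, "BH")`; `NA` p-values (filtered genes) are never rejected
  and do not count toward $m$.
* `co_regulated_sets()` — direction-consistent intersection of two
  comparisons; conflicting directions fall in neither set.
* `replicate_concordance()` — squared Pearson correlation of
  $\log2(FPKM + 1)$; the transform is a package choice (the study does
  not state its own), and a constant profile yields `NA` rather than a
  spurious value.

## What passing tests do and do not show

The simulator emulates the *design* — genotype-driven multiplicative
expression, triplicate lognormal noise, NB counts, Ct arithmetic,
deterministic bands — with known ground truth, so the suite can assert
exact zero-noise recovery, ≥90% exact-set recovery at the default
stochastic scenario (200 genes, β = 1.5, σ = 0.15, n = 3), type-I error
bands, and DE-screen FDR ≤ 0.10 with power ≥ 80% at log2FC 2. Real data
differ in ways the generator deliberately omits: heterozygous or
incompletely fixed lines, primer efficiency below 2, reference-gene
drift, correlated replicates, AS-PCR artifacts, and tagwise dispersion.
Passing tests validate the inference machinery, not those biological
complications. Problem sizes in the suite (120–5000 genes per property)
were chosen as the smallest that give stable Monte-Carlo margins for each
assertion.

## Known limitations

* Autosome-level resolution only: no QTL intervals, no promoter/enhancer
  semantics, no dominance.
* The printed table's replicate data are unavailable; its rounded
  summaries cannot reproduce every printed flag, which is why the flags
  themselves are authoritative.
* The DE stand-in shares the study's screen *logic* (FDR 0.05,
  two-comparison intersection) but not its software, so the study's
  whole-transcriptome gene counts are not comparable quantities here.
* With three replicates the Welch test is approximate and the exact
  permutation test is non-informative at the 0.05 level; conclusions at
  this depth rest on effect sizes large relative to qPCR noise, as in the
  assayed panel.
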
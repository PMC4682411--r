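---
title: "Ranking kinase dependencies from polypharmacology screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking kinase dependencies from polypharmacology screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karmap)
```

## The problem

Small-molecule kinase inhibitors are promiscuous: a compound marketed
against one kinase typically binds dozens of others at pharmacologically
relevant concentrations. When a high-throughput viability screen shows
that a cell line is sensitive to an inhibitor, the nominal target is
therefore a poor guide to *which kinase the cell actually depends on*.
`karmap` deconvolutes this by integrating three data sources per cell
line:

1. a **drug screen** — EC50 (µM) per (cell line, compound);
2. a **quantitative binding panel** — Kd, IC50 (µM) or percent
   inhibition per (compound, kinase);
3. a **log2 expression table** — to discard kinases the cell line does
   not express.

The intuition: a kinase the cell line depends on should be inhibited
preferentially by the compounds the cell line is *sensitive* to, and
rarely by the compounds it is *insensitive* to.

## The dependency ranking model

### Sensitivity bins

For each cell line, every usable compound is assigned to one of five
ordinal bins from its EC50, bin $b$ covering
$\mathrm{EC50} \in (c_{b-1}, c_b]$ µM with $c_0 = 0$, $c_5 = \infty$.
Each bin carries points awarded to every kinase target of the compound:

| bin | default EC50 range (µM) | points |
|-----|--------------------------|--------|
| 1   | (0, 0.1]                 | +20    |
| 2   | (0.1, 1]                 | +10    |
| 3   | (1, 5]                   | +5     |
| 4   | (5, 10]                  | 0      |
| 5   | (10, ∞)                  | −10    |

Bins 1–3 are "sensitive", bins 4–5 "insensitive"; bin 5 carries a
penalty. The point values are fixed by the method; the EC50 *boundaries*
separating the bins are not part of the published description, so they
are configuration: the defaults above encode absolute potency semantics
(sub-100 nM is a strong hit, above 10 µM is inactive at screening
doses), and a per-cell-line quantile mode (20/40/60/80th percentiles of
the observed EC50s) is provided for screens whose potency range is
globally shifted. A compound with a blank EC50 was *not tested* and is
skipped; the `GT_MAX` sentinel means *tested but inactive at the top
dose* and forces bin 5 — the two cases must contribute differently,
which is why the reader keeps them distinct.

### Dichotomization and usability

Binding measurements are dichotomized: a kinase is *inhibited* by a
compound iff Kd/IC50 $<$ 1 µM or percent inhibition $>$ 85 (strict
inequalities; both thresholds configurable). A compound is *usable* if
it appears in both the screen and the binding panel and inhibits at
least one kinase — a screened compound with no binding profile carries
no target information and is dropped.

### Expression filter

Kinases whose gene has log2 expression below a cutoff in the sample are
removed before scoring. The cutoff default is the 25th percentile of the
sample's per-gene values (platform-adaptive; an absolute cutoff is
available). Two deliberate conventions:

* **complex labels** such as `CDK2/cyclin A` are parsed so that the
  *first* slash component (the kinase gene) drives the expression
  lookup — cyclins and p25 are regulatory partners, not kinase genes;
* kinases **absent from the expression table are kept** and flagged
  `unmeasured` rather than silently dropped: losing a potential target
  to platform coverage would be invisible to the user otherwise.

### Scoring and association testing

The raw score of kinase $k$ is
$S(k) = \sum_{c\,:\,c \text{ inhibits } k} \mathrm{points}[\mathrm{bin}(c)]$
over usable, binned compounds — an integer combination of the point
values. For inference, each kinase gets the 2×2 table

|                 | sensitive (bins 1–3) | insensitive (bins 4–5) |
|-----------------|----------------------|------------------------|
| inhibited       | $n_{11}$             | $n_{12}$               |
| not inhibited   | $n_{21}$             | $n_{22}$               |

tested with Pearson's chi-square (1 df, no continuity correction) and a
**one-sided** Fisher exact test for enrichment of sensitive compounds
among the inhibitors. One-sidedness is a design choice: dependency is a
directional hypothesis, and a kinase hit only by *insensitive* drugs
must never be called significant (the direction is still reported in its
own column). Because both tests are named by the method but only one
p-value is ranked on, the reported p is the Fisher p whenever any
expected cell count is below 5 and the chi-square p otherwise — the
standard small-count rule; both are always emitted. A degenerate margin
(all compounds sensitive, or no inhibitor) leaves the chi-square
undefined; it is reported as 1 and the Fisher p used.

Kinases are ranked by reported p ascending, raw score descending, label
ascending (the label tie-break makes output deterministic). A kinase is
flagged significant when reported p $< \alpha$ (default 0.05, matching
the method's criterion; no multiplicity correction on the flag, but a
BH-FDR column is emitted) *and* its raw score is non-negative — the
bin-5 penalty encodes evidence against dependency, so a net-negative
kinase is never called dependent regardless of its p-value.

## The connectivity map

The second module answers the converse question: given a set of kinases
a cell line depends on (conventionally the top five of the ranking),
which inhibitor best covers that set?

Each inhibitor's binding profile becomes a **reference profile**: its
kinases ranked most-potent-first (Kd/IC50 ascending, percent inhibition
descending; potency ties broken alphabetically). Profiles from different
source panels are never merged — the readouts are incommensurable — and
a profile mixing readouts is an error.

For a query of which $t$ kinases match a profile of length $n$ at ranks
$V_1 < \dots < V_t$, the enrichment statistic is the signed running
maximum used in connectivity-map analysis:

$$a = \max_{j}\left(\frac{j}{t} - \frac{V_j}{n}\right),\qquad
  b = \max_{j}\left(\frac{V_j}{n} - \frac{j-1}{t}\right),\qquad
  \mathrm{KS} = \begin{cases} a & a \ge b\\ -b & \text{otherwise}\end{cases}$$

The tie $a = b$ resolves to the positive side: that is what guarantees
the normalized score below equals 1 *exactly* when the query occupies
the top $t$ ranks, including the degenerate $n = t + 1$ profile. The
**connectivity score** maps the statistic onto the documented 1
(maximal efficacy) … 0 (minimal efficacy) range by dividing the positive
part by its achievable maximum:

$$\mathrm{score} = \frac{\max(0, \mathrm{KS})}{1 - t/n} \in [0, 1].$$

Query kinases absent from a panel are ignored ($t$ shrinks,
`n_matched` is reported); an inhibitor whose panel contains no query
kinase is not connectable (score 0, p 1). An inhibitor whose profile
consists *only* of query kinases trivially scores 1.

### Permutation p-value

The published method filters hits at p $<$ 0.05 without defining the
null, so the package defines it permutation-style and
assumption-free: the null is the connectivity score of a uniformly
random same-size kinase subset of the profile, and

$$p = \frac{1 + \#\{\mathrm{null} \ge \mathrm{observed}\}}{1 + n_{\mathrm{perm}}}$$

with $n_{\mathrm{perm}} = 10{,}000$ by default and a mandatory seed.
This counting p is valid but *super-uniform*: null scores are discrete
and clipped at 0, so roughly half of all null queries share the score-0
atom and receive p ≈ 1. A plain uniformity test on such p-values would
reject for the wrong reason. `permutation_p(randomized = TRUE)`
therefore also offers the tie-randomized form
$p = (\#\{\mathrm{null} > \mathrm{obs}\} + U\,(1 + \#\{\mathrm{null} =
\mathrm{obs}\}))/(1 + n_{\mathrm{perm}})$, $U \sim \mathrm{U}(0,1)$,
which is exactly uniform when the observed score is itself a null draw.
The calibration tests check uniformity on the randomized form and
super-uniformity (type-I control) on the default form; ranking and
filtering always use the default.

## Reporting

The per-cell-line rankings condense to a cell-line × kinase matrix of
raw scores restricted to kinases significant somewhere (unscored cells
are 0). Columns are standardized to mean 0, SD 1 — population SD, with
zero-variance columns set to 0 rather than NaN — and both axes are
clustered (Euclidean distance, average linkage by default; both
configurable, as the original analysis does not state them). Canonical
outputs are text: the z-scored TSV, leaf orders, and newick merge trees;
a heatmap PNG is a convenience only. The EC50 counterpart clusters
log10(EC50) with missing/inactive cells imputed to the maximum tested
concentration (declared in the output), since raw µM distances would be
dominated by the weakest compounds.

## The synthetic generator

`simulate_kinase_screen()` emulates the joint structure of the three
inputs with known ground truth, so the whole pipeline is testable
without any external download. Default dimensions mirror the
application's scale (12 cell lines × 72 usable compounds × 300 kinases);
the validation experiments in the test suite run a reduced
4 × 20 × 50 scale so 200-replicate sweeps stay inside a few minutes on
one CPU.

Generator design, chosen once as realistic for this data type:

* **binding**: each compound measures 1 + Poisson(3) kinases with
  log10 Kd ~ N(−0.3, 0.8) (µM) — a promiscuity profile in which a
  typical compound has a couple of sub-µM targets;
* **planted dependencies**: one kinase per cell line (configurable map);
  each planted kinase is guaranteed six sub-µM hitter compounds, the
  kind of target coverage a well-represented kinase has in a
  ~20-compound usable set;
* **screen**: baseline log10 EC50 ~ N(1.0, 0.25) — ~10 µM, landing
  non-hitters in bins 4–5 — divided by `effect` (default 20×) for
  compounds that potently hit the cell line's planted kinase; EC50s
  above the 30 µM top dose become `GT_MAX` entries and 2% of cells are
  blanked as untested;
* **expression**: planted kinases always expressed (log2 mean 8,
  SD 0.5); 30% of the others silenced (mean 3), which the default
  25th-percentile cutoff removes.

Everything is driven by one integer seed through a pinned generator
(Mersenne-Twister, inversion normals), recorded in the output metadata;
the caller's RNG state is preserved. A consistency check at generation
time asserts that every planted pair has at least one sub-µM compound.

What the generator does **not** emulate: kinome phylogeny and
binding-site similarity (real off-target sets are correlated, not
uniform), dose–response curve noise, batch structure in expression, and
panel-specific kinase coverage. Passing the recovery and calibration
tests therefore demonstrates that the statistics behave as designed
under the stated generative model — not that real screens meet that
model.

## Validation performed by the test suite

* the one-sided Fisher p equals exhaustive hypergeometric enumeration on
  every 2×2 table with total ≤ 20 (tolerance 1e−12), including the
  analytic case $[[5,0],[0,5]] \to 1/252$;
* the KS statistic equals a brute-force loop on every profile/query
  configuration with $n \le 8$, $t \le 3$, and the connectivity score is
  1 exactly on top-$t$ placements;
* planted-dependency recovery: over 200 replicates at the reduced scale
  and default effect sizes, the planted kinase is ranked #1 with
  reported p < 0.05 in at least 95% of cell-line instances;
* type-I calibration: on matched null simulations at most 7% of kinase
  records are flagged at α = 0.05 (one-sided exact tests are
  conservative, so the observed rate is far lower), and randomized
  permutation p-values pass a uniformity goodness-of-fit test at
  α = 0.01;
* a 6-drug/4-kinase/2-cell-line toy fixture reproduces a hand-computed
  golden ranking and z-scored matrix exactly.

`scripts/acceptance.R` recomputes all of these from scratch against the
installed package and writes them as JSON.

## Numerical and degenerate-input conventions

* dichotomization and bin edges use the stated strict/half-open
  conventions everywhere; boundary values are decided, not fuzzy;
* compound identifiers match case-insensitively (first-seen spelling is
  kept); gene symbols and kinase labels are upper-cased on ingest;
* tables written by the package print doubles with 17 significant
  digits, so read–write–read is a fixed point;
* an all-zero margin 2×2 table reports chi-square p = 1; an empty
  usable-compound set is a hard error, while a cell line with no
  binnable compound yields an empty ranking with a warning;
* `hclust` merge order and the alphabetical tie-breaks make every
  output deterministic for fixed inputs.

## Limitations

The ranking treats compounds as exchangeable evidence units: correlated
chemotypes (many analogs of one scaffold) overweight their shared
targets. Binding panels cover different kinase subsets, so scores are
comparable within a cell line but only loosely across data sources.
The significance criterion is per-kinase at fixed α with no
multiplicity adjustment, faithful to the original method; users wanting
family-wise control should filter on the emitted FDR column instead.

## A worked run

```{r toy}
d <- system.file("extdata", "toy", package = "karmap")
res <- run_kar(read_drug_screen(file.path(d, "screen.tsv")),
               read_binding(file.path(d, "binding.tsv")),
               read_expression(file.path(d, "expression.tsv")),
               read_kar_config(file.path(d, "config.yaml")))
res[["CL1"]][, c("rank", "kinase", "raw_score", "reported_p", "significant")]

zscore_columns(score_matrix(res))
```
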
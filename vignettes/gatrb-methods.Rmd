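---
title: "Mining TRB repertoires for treatment-response biomarkers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining TRB repertoires for treatment-response biomarkers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`gatrb` implements an analysis chain for bulk T-cell receptor beta (TRB)
repertoires in treated multiple-sclerosis cohorts: discovery of public,
treatment-associated clonotypes ("Enhanced Sequences", ES) by case/control
comparison; one-wildcard motif expansion and multi-cohort replication; HLA
carrier imputation from repertoire features; clonal breadth/depth biomarker
scoring and exposure prediction; and treatment-by-HLA interaction modelling
of clinical outcomes. Because suitable raw repertoires and trial records are
not freely redistributable, the package ships a first-class synthetic cohort
generator that emulates the statistical structure these analyses assume, so
every stage is testable end to end.

# Data model

A *rearrangement* is a unique nucleotide-level V(D)J product with a template
count (a proxy for cell count); a *clonotype key* is the triple (CDR3
amino-acid junction, V gene, J gene). Several nucleotide rearrangements can
encode one key (convergent recombination). All denominators are defined on
*productive* rearrangements, deduplicated at **nucleotide** level:
`R_unique` (unique productive rearrangements) and `T_total` (productive
templates) are always recomputed from the rows and never trusted from a
file. Gene calls are canonicalized to allele-stripped, zero-padded names
(`TRBV5-6*01` → `TRBV05-06`) so that keys match across sequencing dialects.

# Enhanced-Sequence discovery

Within each cohort, every observed key is tested for enrichment in exposed
cases by a one-sided Fisher exact test on presence/absence (upper
hypergeometric tail). Keys with p < 0.001 are ES candidates. Each candidate
seeds one-wildcard motifs: at every interior junction position (the
conserved C/F flanks are never wildcarded, configurable) the residue is
replaced by `x`, all observed keys of the same V, J and length matching the
pattern become members, and the motif's *combined p-value* is the same
one-sided test applied to the union presence of its members. A motif is
retained in a cohort when its combined p is below 1e-4 **and** strictly
below the p-value of every individual member — a motif that cannot beat its
best member adds nothing. "Combined p-value" is interpreted as
union-presence enrichment; this is the reading consistent with requiring
improvement over any single member. Finally, candidates (keys and motifs)
must be significant in at least two cohorts. No false-discovery-rate
correction is applied by default: stringency comes from the dual filter of
a low threshold plus cross-cohort replication; a Benjamini–Hochberg mode is
available for users who want adjusted p-values reported.

Two points the discovery contract leaves open are exposed as configuration
rather than guessed: whether replication uses each cohort's own p < 0.001
bar or a different one (`p_seq`), and whether motifs are seeded from all
keys or only ES keys (seeded from ES, the narrower reading).

# HLA imputation and ES-to-HLA assignment

Carriage of an HLA allele is imputed from a repertoire by a two-covariate
logistic model: the count of allele-associated feature clonotypes present,
and log `R_unique` (controlling for sampling depth). Feature clonotypes are
selected from candidates by one-sided Fisher carrier enrichment (default
p < 1e-4, configurable — the upstream feature-selection procedure of
production HLA classifiers is not restated here, so the threshold is
explicit). Performance is reported as 5-fold cross-validated AUROC, and the
holdout benchmark (`hla_imputation_benchmark()`) reproduces the > 0.9
operating point under the simulation settings described below.

Each discovered ES is then assigned to an allele by testing its presence
against every allele label (typed labels take precedence over imputed ones
when both exist) with one-sided Fisher tests, taking the most significant
allele; motifs take the most significant allele among their members.
Categories follow the p < 1e-4 (assigned) / p < 1e-3 (uncertain) rule, and
ties in the minimal p are reported jointly rather than broken silently.

# Biomarker scores and exposure prediction

For a pattern (a set of keys and motifs), *clonal breadth* is the fraction
of unique productive rearrangements matching the pattern and *clonal depth*
the fraction of productive templates matching; breadth is also reported per
10^6 unique rearrangements. Exposure prediction evaluates how well breadth
and depth separate exposed from unexposed subjects **within the pattern's
own HLA carrier stratum**, by rank-statistic AUC (midrank ties, equal to
trapezoidal ROC integration). The 95% CI uses the DeLong variance method —
deterministic and standard; a stratified bootstrap is available by flag.

*Productive clonality* is `1 - H/ln(R_unique)` with `H` the Shannon entropy
of productive template frequencies (natural logarithm; the base cancels in
the ratio). A single-clone repertoire is defined to have clonality 1.
*Expansions* between a baseline and a treated sample are nucleotide
rearrangements absent at baseline but ranked in the treated top 100 by
templates; ranking ties are broken lexicographically by nucleotide sequence
so the top-100 boundary is deterministic, and non-productive rearrangements
are eligible (the rule is nucleotide-level), configurably.

# Clinical interaction models

Carrier-level linkage disequilibrium between two alleles is summarized by
normalized D' computed on carrier frequencies; the six published cohort
tables bundled with the package (`cohort_carrier_counts()`) reproduce the
printed values (0.27, 0.26, 0.14, 0.10, 0.31, 0.37) exactly at two
decimals, which is also the package's validation that the carrier-level
convention is the right one. The absolute value is reported, as the
published values are nonnegative.

Outcome models use the shared covariate set: min-max-normalized age and
disease duration (scaled within each analysis dataset; scaling does not
change other covariates' effects), sex, treatment indicators, HLA carrier
indicators, and treatment-by-HLA interactions. Continuous outcomes use
ordinary least squares. Time-to-first-event uses Cox partial likelihood
with Efron tie handling (a default the source description does not fix;
Efron is the standard choice for relapse data with tied days). Recurrent
relapses use the Andersen-Gill counting-process Cox model with robust
sandwich standard errors clustered by subject — not stated upstream either,
but required for valid recurrent-event inference. Kaplan-Meier curves carry
Greenwood variance. Schoenfeld residuals are provided as the
proportional-hazards diagnostic. Cross-sectional group comparisons can be
preceded by exact matching on sex, HLA indicators and quantile-binned age;
matching weights (1 for the group of interest, the within-stratum group
ratio otherwise) are returned so matched margins balance exactly. The
upstream description of matching mixes an exact method with a model-based
distance; exact matching is what is implemented here, and the discrepancy
is documented rather than hidden.

These standard fits are delegated to `survival`, `stats::lm`/`glm` and
`pROC`; the package's own layers are the discovery, scoring, assignment and
simulation logic around them, plus the carrier-level D' statistic.

# The synthetic cohort generator

The generator is the package's study stand-in, not a test fixture. Its
defaults are fixed once to the study conditions:

* **Cohorts**: three discovery cohorts of 58/211, 75/234 and 71/978
  cases/controls, each with its published carrier frequencies and
  carrier-level D' for HLA-A\*03:01 / HLA-DRB1\*15:01 (0.31/0.48 at 0.31;
  0.33/0.44 at 0.27; 0.49/0.47 at 0.10).
* **Repertoires**: unique productive rearrangement counts are
  negative-binomial around 3000 (dispersion 12) drawn from a shared
  60000-key public pool; clone sizes follow a discrete power law with
  exponent 2.0 (no clone-size law is stated upstream; a power law is the
  standard repertoire shape and gives realistic top-100 dynamics); 12% of
  rows are non-productive.
* **Planted signal**: 65 + 35 + 5 treatment-associated keys on the A, B
  and unrestricted backgrounds, present at 0.02 in unexposed repertoires
  and 0.30 in exposed carriers of the matching allele; a single
  multiplicative synergy factor (default 1.5) raises the A-pattern in
  double carriers — the synergy is only shown graphically upstream, so the
  factor is a documented free choice. 100 imputation feature keys per
  allele at 0.30 carrier / 0.015 non-carrier presence.
* **Longitudinal pairs**: the treated sample is the baseline sample under
  resampling (templates re-drawn, 5% of clones lost), plus newly recruited
  pattern keys and ~5% background churn entering at one template, plus a
  configured number of expansion clones (default 12) pushed into the top
  100.
* **Clinical outcomes**: recurrent relapses from a Poisson intensity of
  0.3 events/year over 3 years with multiplicative effects (interaction
  hazard ratios 0.66/0.67 for the GA and GA+IFN arms); first-relapse times
  exponential with one-year administrative censoring at intensity 1.0
  events/year — this intensity is calibrated so that the simulated
  first-event fits reproduce the published interval width for the
  interaction (SE of the log hazard ratio ≈ 0.435), which pins the
  information content of the simulated cohort to the published one;
  continuous outcomes from linear models with interaction effects -0.34
  (annual EDSS change, noise SD 0.9) and -1.34 (MSSS, noise SD 2.0).

What the generator does **not** emulate: V(D)J generative sequence biology
(junctions are random strings with conserved flanks), sequencing error,
PCR amplification bias, batch effects, shared-ancestry structure beyond the
two modelled alleles, and treatment switching. Passing tests therefore
demonstrate that the analysis chain recovers planted structure at realistic
sizes and noise levels — not that it is robust to assay artifacts absent
from the simulation.

A note on arm sizes for the recurrent-event recovery experiment: the
combination-trial relapse analysis tabulates 112/56, 112/60 and 258/95
subjects per arm-by-HLA group (693 in total), while the genotype table for
the same trial lists 699 patients; the 693 with relapse data are what the
model sees, so that allocation is used.

# Numerical choices and degenerate inputs

Fisher tests are computed as vectorized hypergeometric tails (`phyper`),
exact and fast for the ~60000 simultaneous tests discovery performs; the
test suite holds them against both an explicit tail-sum oracle and
`fisher.test`. Cox fits iterate to a gradient tolerance of 1e-9 with a cap
of 50 Newton iterations; constant covariates, overlapping intervals and
event-free data are rejected with specific errors, and monotone-likelihood
(separation) warnings are surfaced rather than hidden. Clonality is
undefined for an empty repertoire (error), 1 for a single clone
(convention). D' is undefined at degenerate margins (error) and 0 at exact
independence. Duplicate nucleotide rows are merged with summed templates
under a warning. All generation is a pure function of (configuration,
seed); the pipeline fans a single global seed into fixed per-stage child
seeds so stages can be re-run in isolation.

# Problem sizes in the shipped checks

The test suite and the acceptance script run at the study's stated sizes
where those matter (1627-sample discovery runs across three cohorts;
600-repertoire imputation benchmarks with 480/120 train/holdout splits;
693- and 335-subject clinical simulations), with 3–10 seed replicates for
averaged quantities and 25–50 replicates for the interaction-recovery
experiments. Smaller pools (~6000 keys) and repertoires (~400 rearrangements)
are used only in unit tests of mechanics where absolute scale is
irrelevant.

# Known limitations

* Assignment power for ES-to-HLA mapping depends on the number of samples
  carrying each ES; at small cohort sizes most ES remain "uncertain".
* The Cox interaction estimator is noticeably variable at the published
  group sizes (few events in the smallest arm-by-HLA cell); recovery
  experiments therefore report geometric means over many replicates and
  confidence-interval coverage, not single-fit estimates.
* Exact matching with quantile-binned age leaves residual within-bin age
  drift; finer bins trade balance against sample retention.
* The wildcard expansion considers exactly one wildcard, as specified; it
  will not merge families needing two or more free positions, though the
  Hamming-distance clustering utility can reveal such structure
  descriptively.
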
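---
title: "Detecting parent-specific expression from reciprocal crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parent-specific expression from reciprocal crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psger)
```

## The design

Parent-specific gene expression (PSGE) is an unequal contribution of the
maternally and paternally inherited alleles to a gene's transcript pool.
Detecting it from RNA-seq requires knowing, for every read, which parent
contributed the allele it carries — and separating *parent-of-origin*
effects from *lineage-of-origin* effects (a strain's allele being more
active regardless of which parent it came from). A reciprocal cross
uncouples the two: in family **AE** an Africanized queen is mated to a
European drone, in family **EA** the reverse, so F1 workers of the two
families are genotypically equivalent while parent and lineage swap roles.

Honey bee genetics makes the read-level bookkeeping unusually clean.
Drones are haploid, so at any site where the queen is homozygous for one
allele (`aa`) and the drone carries a different allele (`b`), every F1
worker is heterozygous `ab` with known parental origin for each allele and
a 1:1 maternal:paternal read expectation under the null.
`select_informative_snps()` keeps exactly the `aa x b` and `bb x a`
configurations; heterozygous queens, drones matching the queen, and
multi-allelic sites are dropped, and a heterozygous *drone* call is
treated as a genotyping error rather than salvaged, because it violates
haploidy.

## The per-transcript model

For one transcript in one sample group, each surviving (SNP, library) cell
contributes two observations — the maternal-allele and the paternal-allele
read count. The response is `y = log2(count + 1)`; raw counts are strongly
heteroskedastic and the log transform stabilizes the variance while
keeping the fixed/random structure of a Gaussian linear mixed model (a raw
response remains available via `response = "raw"`). Parent and lineage are
effect-coded,

\[
y = \mu + \beta_P P + \beta_L L + \beta_{PL} (P\!\cdot\!L)
  + u_{\mathrm{snp}} + v_{\mathrm{rep}} + w_{\mathrm{cell}} + \varepsilon,
\]

with \(P = +\tfrac12\) for maternal, \(-\tfrac12\) paternal, and
\(L = +\tfrac12\) for Africanized, \(-\tfrac12\) European, so \(\beta_P\)
is the maternal\(-\)paternal mean difference on the log2 scale. Random
intercepts are fitted for SNP, library and the SNP-by-library cell, by
REML (through lme4), with variance components constrained non-negative; a
component estimated at the zero boundary is set to zero and the model
refit without it.

Two structural points deserve emphasis.

**The cell intercept is load-bearing.** The two parental counts of one
cell share that cell's sequencing depth. Without a cell-level intercept,
depth variability inflates the residual against which the *within-cell*
parent contrast is tested, and the parent test becomes badly conservative
(in the package's null calibration the empirical false-positive rate drops
to ~0.02 and the p-value distribution is visibly non-uniform). With it,
null parent p-values are approximately uniform. This is the package's
reading of "accounting for variance due to SNP and sample replicates":
the pairing of the two alleles within a cell is part of that variance.

**The interaction is aliased with family.** With exactly two reciprocal
families, \(P \cdot L\) is constant within each family (\(+\tfrac14\) in
AE, \(-\tfrac14\) in EA): the interaction column *is* a scaled family
indicator, asserted at design-build time. Because libraries are unique to
a family, \(\beta_{PL}\) is therefore estimated against between-library
variation only. This is a property of the design, not of the
implementation, and it caps the power of any interaction-based test at
small library counts (see *Limitations*).

### Term tests and degrees of freedom

Each term is tested with a Wald statistic \((\hat\beta/\mathrm{SE})^2\).
The default reference distribution is F(1, df) with *between-within*
denominator degrees of freedom: parent and lineage are within-cell
contrasts and use `n_obs - n_cells - 2`; the interaction is a
between-library contrast and uses `n_replicates - 2`. This is the
classical containment-style convention of mixed-model software. The
large-sample chi-square(1) reference (`df_method = "asymptotic"`, also
exposed as `wald_term_test()`) is anticonservative in the far tail at
these replicate counts — enough to contaminate a Benjamini-Hochberg
selection across a thousand transcripts — which is why it is not the
default.

Degenerate fits follow fixed conventions: a design interpolated exactly by
the fixed effects (noiseless data) reports zero variance components and
p = 0 for nonzero coefficients (infinite statistic), p = 1 for zero ones,
flagged `degenerate`; a transcript observed in a single family falls back
to a parent-only fit with `NA` for the lineage and interaction terms.

P-values are adjusted per sample group and per term with the
Benjamini-Hochberg step-up procedure; "significant" downstream always
means q below the false-discovery threshold, default 0.05.

## From fits to calls

Family ratios are computed from pooled raw counts: the maternal fraction
\(R_f\) and Africanized fraction \(Q_f\) sum counts over SNPs and
replicates within family \(f\). Pooling weights SNPs by their coverage and
stays defined for sparse transcripts; a mean-of-per-SNP-ratios variant is
available (`ratio_method = "mean_of_ratios"`) for sensitivity analysis.
By construction \(R_{AE} = Q_{AE}\) and \(R_{EA} = 1 - Q_{EA}\); both
identities are exercised in the test suite.

Three rules, each requiring direction consistency:

* **maternal / paternal PSGE** — parent term significant and
  \(R > 0.6\) (resp. \(R < 0.4\)) in *both* crosses;
* **lineage bias** — lineage term significant and \(Q > 0.6\)
  (Africanized) or \(Q < 0.4\) (European) in both crosses;
* **asymmetric maternal** — interaction term significant and \(R > 0.6\)
  in exactly one cross. A transcript above the threshold in both crosses
  belongs to the first list and is not asym-flagged, so the two asym flags
  are mutually exclusive with each other and with the both-cross case.

A transcript may legitimately carry a parent and a lineage flag at once;
the lists are not forced to be disjoint. The 0.6 ratio threshold and the
0.05 q threshold are configuration values, not constants. Note one
subtlety: the asymmetric flag is *not* monotone in the ratio threshold
(raising it can move a both-cross transcript into the one-cross case);
only the both-cross rules are.

Follow-up statistics mirror the downstream questions: a Storer-Kim exact
unconditional two-proportion test compares the numbers of maternally and
paternally biased transcripts per group (framed as x successes out of the
transcripts tested in that group, on both sides), pairwise list overlap
across sample groups uses the inclusive upper-tail hypergeometric
probability on the *shared tested universe*, and a generic 2x2 Pearson
chi-square (no continuity correction by default, flag exposed) serves
membership questions such as mitochondria-localized gene lists supplied as
plain text files.

## The synthetic-data generator

`simulate_dataset()` emulates the study design end to end: two reciprocal
families; pooled larvae (2 libraries per family), pooled adults (2), and
individual brains (3); biallelic SNPs on two synthetic chromosomes with
transcripts as contiguous blocks; the European allele as the reference.
Per transcript it draws a truth class, `1 + Poisson(2)` SNPs, and for each
(SNP, library) cell a negative-binomial total depth (mean 50, size 8 — a
realistic level of library/locus depth overdispersion) and a beta-binomial
maternal count (overdispersion `rho = 0.02`) at the class- and
family-specific expected maternal fraction: 0.5/0.5 for null, 0.8/0.8 for
maternal at the default effect size, 0.8 in exactly one family for the
asymmetric classes, and for lineage classes the fraction translates
through the family-lineage map (the maternal allele is Africanized only in
AE). Reference-mapping bias is modeled as one-sided read loss: each read
carrying the Africanized allele is dropped with probability `b`,
mimicking alignment to a European-derived reference. Everything is
deterministic given the seed, and a truth table with expected per-family
fractions is emitted alongside the VCFs, SNP table and counts.

What the generator does *not* emulate: read-level errors, splicing,
positional coverage structure within transcripts, genuine biological
covariance between transcripts, or ascertainment of SNPs from finite
parental sequencing. Passing tests on these simulations therefore
demonstrate the statistical machinery under the stated noise model, not
robustness to every artifact of real libraries.

`simulate_ascertainment_null()` runs the full pipeline on an all-null,
mapping-biased dataset. The signature it checks: one-sided read loss
shifts *lineage* ratios in the same direction in both families but shifts
*maternal* ratios in opposite directions, so lineage-biased calls inflate
with `b` while parent-of-origin calls stay near the nominal null rate.
At `b = 0.3` the expected Africanized fraction is \(0.35/0.85 \approx
0.41\), right at the 0.4 call threshold, so the lineage call rate is
moderate rather than dramatic — the direction of the contrast, not its
size, is the diagnostic.

## Problem sizes and verification

The test suite builds every fixture in code. Exact checks (informative-SNP
enumeration over all six biallelic configurations, Storer-Kim against a
naive double-loop enumeration for all outcomes with n up to 12,
hypergeometric tails against direct combinatorial sums, classification
rules against a truth-table oracle, BH against an independent step-up,
noiseless mixed-model recovery to 1e-8) are complemented by Monte-Carlo
checks at the study's own design: null calibration at 1000 transcripts
(empirical parent false-positive rate, BH selection size, KS distance from
uniformity), maternal-class recovery and false-discovery proportion at 500
transcripts with 10% signal, and the mapping-bias direction property at
500 transcripts — sizes chosen to estimate rates with usefully small
Monte-Carlo error while keeping a full run in minutes.

## Limitations

* With two reciprocal families the interaction contrast is confounded with
  the family contrast; its test compares six library means. At the study's
  library counts (2-3 per family) the one-cross "asymmetric maternal"
  class at fractions 0.5/0.8 produces an interaction effect of roughly
  0.6 on the coefficient scale against a standard error of roughly the
  same size, so sensitivity for that class is very low at desk scale.
  Recovering it reliably needs many more libraries per family (or a
  design with more than two families). The classification rule is
  implemented and tested; its statistical power is a design property.
* Wald-type tests with between-within df are an approximation; they are
  calibrated in the package's null checks but are not an exact
  finite-sample procedure.
* The Gaussian model on `log2(count + 1)` discards the mean-variance
  relation a count model would exploit; at very low depths a
  binomial/beta-binomial likelihood on allele fractions would be more
  efficient. The coverage filter (default: at least 10 reads per SNP per
  library) keeps the analysis in the regime where the approximation is
  serviceable.
* Single-family transcripts are reported (parent-only fit) but can never
  satisfy the both-cross rules; they are visible in the output rather than
  silently dropped.
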
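---
title: "Methods: a candidate-gene PCR-RFLP association pipeline for cattle body measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a candidate-gene PCR-RFLP association pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`cgassoc` re-implements, as a tested and reusable pipeline, the complete
computational chain of a candidate-gene SNP association study in cattle:

1. **in-silico PCR-RFLP genotyping** -- primer location, amplicon
   extraction, restriction digestion, genotype calls from gel band
   patterns;
2. **marker diversity statistics** -- genotype/allele frequencies, gene
   heterozygosity He, effective allele number Ne, polymorphism information
   content PIC, and the Hardy-Weinberg chi-square screen;
3. **fixed-effects association** -- OLS fits of
   `Y = mu + G + F (+ B) + e`, genotype least-squares means with standard
   errors, and Duncan multiple-range letters at two display levels;
4. **relative expression** -- the 2^-ddCt method with a reference gene and
   a calibrator tissue.

It ships the three KAT2B assays (g.T61908C by HindIII; g.T62131C and
g.C73406T by ApaI) genotyped in four Chinese cattle breeds (Qinchuan
n = 658, Fu n = 52, Yak n = 48, Chaidam n = 69; 827 females in total), the
published per-breed diversity table for those markers, and a synthetic-data
generator that emulates the study design so every stage is exercised
end-to-end without any external data.  The numbered scripts under
`analysis/` narrate one full run; every computation they perform lives in
the package and is unit-tested.

# The RFLP model

An assay couples a primer pair (1-based inclusive coordinates, the
convention of published primer tables), a restriction enzyme and an
allele-to-cut-state map.  The amplicon runs from the forward primer's 5'
end to the reverse primer's 5' end, so its length is
`reverse_end - forward_start + 1`; for the shipped assays this gives 78,
218 and 314 bp, which equal the undigested band sizes on the published
gels.

Digestion scans the top strand only.  Both shipped enzymes are palindromic
(HindIII `A^AGCTT`, ApaI `GGGCC^C`, standard REBASE definitions), for which
a top-strand scan is complete; non-palindromic definitions are rejected at
construction rather than silently mishandled.  Primer matching is exact --
no mismatches, no IUPAC codes -- because the assays provide exact primers;
thermodynamic annealing models are out of scope.

A diploid lane shows the union of both haplotypes' fragment sets with
duplicate lengths collapsed, since a gel reports the presence of a length
and not its dosage.  Calls are therefore: full-length band only -> uncut
homozygote; the assay's cut fragments only -> cut homozygote; the union ->
heterozygote; anything else is an `uncallable_pattern` error, never a
guess.

For g.T61908C the HindIII site is completed by the forward primer's 3'
end (`...AAGCT`) plus the SNP base, so the T allele cuts 21 bp from the
amplicon start (21 + 57 bp fragments); the two ApaI assays place the SNP
inside a `GGGCCC` site 27 bp into the amplicon (27 + 191 and 27 + 287 bp).
These geometries are encoded in `kat2b_assays()` and verified round-trip in
the tests for all nine genotype-by-assay combinations.

# Diversity statistics

With allele frequencies `p_i`:

* `He = 1 - sum(p_i^2)` (Nei's gene diversity),
* `Ne = 1 / sum(p_i^2)`,
* `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2` (the Botstein form;
  for two alleles `PIC = He - 2 p^2 q^2`),

with the conventional classification low (`PIC < 0.25`), mid
(`0.25 <= PIC <= 0.50`), high (`PIC > 0.50`).  Recomputing these from the
published allele frequencies reproduces all 12 published marker-by-breed
rows at the table's two-decimal precision (`analysis/03_diversity.R` and
the acceptance tests perform this check).

The HWE test compares observed genotype counts against `(n p^2, 2 n p q,
n q^2)` formed from the *observed* allele frequencies, `chi^2 =
sum((O - E)^2 / E)` on 1 df for a biallelic marker.  No continuity
correction is applied by default -- the plain three-class statistic is the
textbook default -- but Yates' correction is available as a toggle.
Markers with more than two alleles generalise with `k(k-1)/2` df and are
flagged experimental.

**A reproducibility caveat the pipeline surfaces.**  Reconstructing integer
counts from the published genotype frequencies (round, let the largest
class absorb the remainder) and retesting reproduces only 7 of the 12
published equilibrium verdicts.  The discrepancies are not borderline in
every case: the largest breed's g.T61908C row prints a heterozygote
frequency of 0.61 against an equilibrium expectation of about 0.49 at
n = 658, a departure (chi-square about 38) that no variant of the test --
plain, continuity-corrected, or exact -- would call equilibrium.  The
published verdicts are therefore internally inconsistent with the published
frequencies, and the pipeline reports the honest recomputation instead of
matching the printed calls.  `analysis/03_diversity.R` prints both tallies.

# Association model and Duncan letters

The fitted model is `Y = mu + G + F (+ B) + e` by OLS with treatment
coding.  Per-breed analyses drop the breed term (it is inestimable within
one breed); a pooled analysis keeps it.  Missing trait values are dropped
casewise.  Genotype LS means are predictions averaged with equal weight
over the levels of the other fixed terms; their standard errors come from
the design-based covariance of that estimable function (`c' V c`), which
reduces to `sqrt(MS/n)` in a balanced one-way design.  The tests verify
the LS means and SEs against `emmeans` on covariate-bearing designs.

Duncan's multiple range test orders the `k` genotype means descending and
tests spans of `p` means against the critical range

```
R_p = q(1 - alpha_p, p, df) * sqrt(MS / n_h),   alpha_p = 1 - (1 - alpha)^(p - 1)
```

where `q` is the studentized-range quantile and `n_h` the harmonic mean of
the group sizes in the span (the classical unequal-n behaviour of the
mainstream GLM packages; a per-pair variant is exposed as an option).  A
span that fails its test is declared homogeneous and none of its sub-spans
is tested -- the protection rule.  Letters are assigned to the maximal
homogeneous spans in descending-mean order; lower-case letters display the
0.05 level and upper-case the 0.01 level.  Because critical ranges grow as
alpha shrinks, the 0.01 grouping can never be finer than the 0.05 grouping
(property-tested).

Numerical choices:

* studentized-range quantiles are computed by root-finding on
  `stats::ptukey` to a tolerance of 1e-8 on the quantile, tight enough
  that the two-group identity `q(alpha, 2, df) = t(alpha/2, df) * sqrt(2)`
  holds to about 1e-6 for df >= 3 (the distribution function itself is the
  accuracy limit at df = 2);
* a residual MS at floating-point noise level is clamped to zero and the
  fit flagged saturated; with `MS = 0` comparisons are exact, with ties
  sharing a letter;
* rank-deficient designs beyond estimable LS means raise an `aliasing`
  error; zero residual df raises a `saturation` error.

**Row-level significance.**  A marker-by-trait row is flagged significant
by the genotype term's extra-sum-of-squares F-test at alpha, the way GLM
software is conventionally used (the GLM decides significance, the range
test annotates *which* genotypes differ).  This is a deliberate design
choice: under a 3-group null, Duncan's protected full-range test rejects at
rate `1 - (1 - alpha)^2` (about 0.0975 at alpha = 0.05) *by construction*,
so a letters-based flag could not have the nominal type-I rate; the F-test
flag does, and the acceptance suite verifies 0.05 +/- 0.02 over 800 null
simulated rows.  Duncan letters are reported alongside in every row.

The published association table prints neither per-genotype n nor error
df, so its exact means and SEs cannot be recomputed.  What can be checked,
and is: reading the published Fu body-length row's dispersions as
within-genotype SDs (at 7-10 cm with group sizes of 11-29, true standard
errors of that magnitude would imply within-group SDs of 24-50 cm --
implausible for body length, so the printed "SE" label is taken as a
mislabel), pooling them (MS about 70.4 on 49 df) and applying the range
test reproduces the printed letter topology exactly: TT (89.73) `a`,
CC (84.00) `ab`, TC (82.86) `b`.

No multiple-testing correction is applied across traits and markers by
default, matching common practice in candidate-gene studies; a Bonferroni
toggle exists.

# Expression

Technical replicates are averaged on the Ct scale (the Livak convention);
`dCt = Ct_target - Ct_reference` per sample, `ddCt` subtracts the
calibrator group's mean `dCt`, and the fold change is `2^-ddCt` with
amplification efficiency fixed at perfect doubling (efficiency-corrected
variants are out of scope).  Two exact invariants are tested: a global Ct
shift applied to both genes in all samples leaves every fold change
unchanged, and `log2(fold) = -ddCt` identically.  Group summaries are the
mean fold change +- SE over biological replicates; the published error-bar
convention is unstated, so SE was chosen once.  A per-tissue t-test between
stages mirrors the single-asterisk display of expression profiles; it is
descriptive output, not an acceptance surface.

# The synthetic generator

The generator *is* the study conditions, not a tuning dial:

* **breeds and sizes**: Qinchuan 658, Fu 52, Yak 48, Chaidam 69;
* **allele frequencies**: the published per-breed frequencies of the three
  markers;
* **HWE departure**: a single inbreeding coefficient `F`, giving class
  probabilities `(q^2 + Fpq, 2pq(1 - F), p^2 + Fpq)`; `F = 0` (exact HWE)
  is the default since only categorical equilibrium verdicts were
  published.  `F` spans heterozygote deficits and excesses and is
  feasibility-checked (`F >= -p/q`, `-q/p`);
* **farms**: the study does not state farm counts or effect sizes; the
  default is 3 farms with offsets of +/- 0.4 within-trait SD, a
  placeholder of realistic magnitude, not an estimate of the study's farms;
* **traits**: means and residual SDs at scales visible in the published
  summaries for two-year-old females (BM 250 +/- 30 kg, BH 128 +/- 6.5 cm,
  BL 86 +/- 8, CW 38 +/- 4.5, CCB 15 +/- 1.3, HIW 42 +/- 5, CG 145 +/- 9,
  WH 127 +/- 7.5), null genotype effects unless a worked example plants
  one;
* **sequences**: uniform-random background, rejection-resampled so each
  primer occurs exactly once per reference, the cut allele's amplicon
  contains exactly one recognition site at the declared offset, and the
  uncut allele's amplicon none.  No claim of biological realism is made
  beyond assay validity.

Seeds are explicit arguments everywhere; generators save and restore the
caller's RNG state, and identical seeds give bit-identical populations,
phenotypes, sequences and pipeline outputs (tested by double-run checksum).

What passing tests therefore show: the *machinery* is correct under the
stated generating model -- i.i.d. genotypes, Gaussian residuals, fixed farm
offsets, linkage-free markers.  What they do not show: robustness to
relatedness or pedigree structure, genotyping error, non-Gaussian traits,
farm-by-genotype confounding, or linkage between markers, none of which
the generator emulates.

# Problem sizes

The shipped analyses and tests run at the study's own scale (827
individuals) for single passes, and at reduced scale for replicated
calibrations: 100 null datasets of n = 200 for the type-I check, 400
replicates of n = 48 for the heterozygote-deficit detection check, 150
replicates of n = 150 for the power check, and 1000 random sequences for
the digestion oracle.  These sizes were chosen so the full suite completes
in a few minutes while keeping Monte-Carlo error well inside the asserted
bands.

# Known limitations

* Single-cut assays only; partial digestion and gel mobility are not
  modelled.
* The HWE exact test is not implemented; the chi-square (optionally
  corrected) is what the pipeline offers.
* Multi-allelic diversity statistics generalise cleanly, but the
  multi-allelic HWE test is experimental.
* Farm is a fixed effect, as in the generating model; random-farm mixed
  models are out of scope.
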
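---
title: "Clonal hematopoiesis and cardiovascular outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal hematopoiesis and cardiovascular outcomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chcv)
```

## The scientific setting

Clonal hematopoiesis (CH) — the expansion of mutated blood-cell clones
with age — comes in two measurable forms: CHIP (somatic driver mutations
in a small panel of leukemia-associated genes, detectable from blood
sequencing at variant allele fraction, VAF, of at least 2%) and mosaic
chromosomal alterations (mCAs: losses, gains and copy-neutral LOH
segments detectable from array intensities, including mosaic loss of Y in
men and of X in women). Both are associated with cardiovascular disease
and mortality in the general population; in cancer patients — already at
elevated cardiovascular risk, partly through therapy — the two forms may
co-occur and possibly interact. `chcv` packages the full analysis chain
for this question: calling CHIP from candidate variants, classifying mCA
calls, building an eligible cohort with per-endpoint survival times,
fitting prevalence and Cox models with a four-category CH exposure, and
quantifying additive and multiplicative interaction.

## The CHIP filter cascade

Candidate variants arrive with read-level evidence: total depth `dp`,
alt depth `ad`, the alt-supporting read-pair orientation counts `f1r2`
and `f2r1`, and the reference context around the site. The cascade
applies, in order (though the per-variant verdicts are order-invariant
and all are recorded in the audit table):

1. **Whitelist**: only variants matching a prespecified list of CHIP
   driver lesions enter. The packaged list (site entries plus
   truncating-variant rules per gene) is a documented stand-in —
   production analyses should substitute their curated list via
   `load_whitelist(path)`.
2. **Depth**: `dp >= 20`, `ad >= 5`, and at least one alt read pair in
   each orientation (`f1r2 >= 1`, `f2r1 >= 1`), the orientation
   requirement guarding against strand-specific artifacts.
3. **Homopolymer**: a site inside or immediately adjacent to a run of 5+
   identical reference bases is removed unless `ad >= 10` and
   `vaf >= 0.08`; slippage artifacts concentrate at and next to run
   boundaries, which is why adjacency counts.
4. **Named artifacts**: TP53 p.P72R and ASXL1 p.P815L are removed
   unconditionally (the former is a common germline polymorphism);
   ASXL1 p.G646Wfs\*12 is removed only at VAF < 0.1, because large
   clones at that hotspot are genuine CHIP. The grammatical scope of the
   VAF condition over the three names is ambiguous in the source
   literature, so both readings are implemented
   (`artifact_scope = "g646fs"` or `"all"`).
5. **Binomial somatic-consistency test**: a missense call in CBL, TET2,
   DNMT3A or TP53 whose allele fraction is consistent with a germline
   heterozygote is removed — exact binomial test of `ad` in `dp` trials
   against 0.5, removal when p >= 0.01. The test is two-sided: a
   germline call is "indistinguishable from 0.5" in either direction.
   Three TET2 hotspots (p.H1904R, p.I1873T, p.T1884A) are exempt as
   established CHIP variants.
6. **Cohort recurrence**: a variant carried by more than 20 participants
   is suspect unless it shows a signature of age-related positive
   selection; carrier status is regressed on age and on *TERT*
   rs7705526 dosage (univariable logistic fits) and the variant is kept
   if either association has p <= 0.1. "Either" is the default because a
   genuine CHIP variant needs only one signature of selection; a
   stricter "both" mode is available (`recurrence_combine`).

A participant's CHIP status aggregates the surviving calls: carrier,
mutation count (classes 1 / 2 / 3+), maximum VAF, and the expanded-clone
flag at VAF >= 10%.

## mCA classification and the exposure

mCA calls (participant, chromosome, loss/gain/cnloh, cell fraction) are
classified into any-mCA, LOY (chrY loss, men only), LOX (chrX loss,
women only), autosomal, and expanded (maximum cell fraction >= 10%).
Source tables state the expansion threshold both as ">= 10%" and
"> 10%"; the methods text is taken as operative (>=), with
`strict_expanded = TRUE` available. The survival exposure is the
four-category factor no CH / CHIP only / mCA only / both, which
partitions the cohort.

## Cohort construction

Eligibility removes participants with a hematologic cancer diagnosed
within 182 days on either side of study entry, participants without
genotypic–phenotypic sex concordance, and one random member of each
relative pair. The three exclusion sets are computed independently on
the full roster and unioned, so the retained set does not depend on the
order of the rules; the relative choice uses a seeded RNG over a
canonically sorted pair list.

Time-to-event records use the prevalent/incident convention: for
cancers diagnosed on or before baseline the clock starts at the
assessment visit, for later diagnoses at the diagnosis date. To absorb
the survivorship distortion that prevalent cases introduce, the number
of days between a prevalent diagnosis and recruitment enters the models
as a covariate (zero for incident cases). Administrative censoring uses
the last registered death date in the dataset — a deliberate, literal
implementation of registry-linked follow-up in which there is no
per-person loss to follow-up; event dates beyond that censoring date are
treated as censored. When a participant has several qualifying cancers,
the earliest one defines the type and date.

## Models and interaction metrics

Prevalence models are maximum-likelihood logistic regressions with Wald
intervals, adjusted for age and sex by default; LOY/LOX analyses are
sex-restricted, dropping sex from the adjustment. Survival models are
Cox proportional-hazards fits (partial likelihood, Breslow tie handling
— ties are sparse in date-resolved data, and Breslow is the convention
of most epidemiological software) adjusted for age, sex, smoking,
chemotherapy, radiotherapy, prevalent CVD, the diagnosis delay, and ten
genetic principal components. Participants with unknown smoking are
kept in descriptive tables but dropped from models (complete-case).

With `h11, h10, h01` the adjusted hazard ratios of both / CHIP only /
mCA only versus no CH:

- `RERI = h11 − h10 − h01 + 1`, the excess of the joint effect over
  additivity of excess risks; 0 under additivity.
- `AP = RERI / h11`, the share of the joint-exposure risk attributable
  to interaction.
- the multiplicative ratio `h11 / (h10 · h01)`, exactly the
  exponentiated product-term coefficient of the Cox interaction
  parameterisation (verified to 10 decimals in the test suite). Some CH
  reports print this quantity under the label "SI"; it is **not** the
  classical synergy index, so the package provides Rothman's
  `S = (h11 − 1) / ((h10 − 1) + (h01 − 1))` separately and labels both
  explicitly.

Confidence intervals propagate the Cox coefficient covariance by the
delta method (analytic gradients; the multiplicative ratio on the log
scale, where it is linear), with a participant-resampling bootstrap as
an alternative; which method produced a published interval is usually
unstated, so both are exposed and the delta method — the cheaper and
conventional choice — is the default. When an exposure cell has no
events the endpoint's metrics are flagged "not reportable" rather than
estimated from a degenerate fit.

## The synthetic cohort generator

The generator draws a biobank-style cancer cohort whose marginal
structure mirrors a published baseline table: ages truncated-normal
(mean 60, SD 7, range 40–71), 45.8% men, smoking
current/never/previous/unknown at roughly 11/49/39/0.6%, chemotherapy
23.3%, radiotherapy 6.3%, prevalent CVD 22.6%. Latent CHIP carriage
follows a logistic model with age log-OR 0.077/year, smoking ORs 0.684
(never) and 0.764 (previous) versus current, chemotherapy OR 1.258; the
intercept is solved numerically so the realised marginal prevalence hits
the 5.5% target. mCA components are generated analogously (LOY 29% of
men, LOX 6.2% of women, autosomal ~4.9%, age log-OR log(1.10)), with
LOY depleted (log-OR log 0.652) and LOX enriched (log 1.242) among CHIP
carriers — reproducing the characteristic anti- and positive
correlations.

No VAF or cell-fraction distributions are published for this setting,
so the defaults are explicit stand-ins calibrated to two printed
fractions: clone VAFs are Beta(1.5, 8.6) left-truncated at the 2%
detection floor, putting ~63% of carriers at VAF >= 10% (the expanded
fraction), and mCA cell fractions are Beta(1, 16), putting ~19% of mCA
carriers above 10% cell fraction. Event times are exponential
proportional hazards — Cox fits are baseline-agnostic, so a richer
baseline would add nothing to parameter-recovery tests — with default
exposure log-HRs per endpoint set near published values (e.g. CHIP-only
HR 1.082 for incident CVD, 1.305 for overall death) and administrative
censoring at a fixed end-of-follow-up date ~15 years after the last
recruitment. The five endpoints are drawn independently; the generator
does not enforce that a CV death is also an any-cause death, which is
irrelevant to the per-endpoint models but means joint-endpoint summaries
should not be read off the synthetic data.

True clones are made *compliant by construction* — depth, strand and
VAF-floor constraints enforced, and allele counts resampled (bounded
decrements) until the binomial test clears for the genes it applies to —
so that calling error can be separated from model error. Labelled decoy
records each violate exactly one identifiable rule (shallow depth, low
alt depth, one-sided strand support, weak homopolymer-run support, the
named artifacts, a germline-like 50% VAF, a non-whitelisted change), and
a reserved recurrent decoy is assigned to ~60 participants independent
of age and TERT, so the recurrence rule removes it with probability
~0.81 under the either-test rule (1 − 0.9², two independent null
p-values) — stochastically, unlike the deterministic classes. Decoy
sites are disjoint from true-clone sites so a locus always has one
consistent evidence profile.

What passing tests on this cohort do **not** show: the generator has no
sequencing-error model, no linkage disequilibrium, no correlated
endpoints, no clone growth over time, and decoys sit cleanly on one
side of each threshold, whereas real artifacts crowd the boundaries.
Perfect filter recovery on synthetic truth is a check of the cascade's
logic, not an estimate of real-world sensitivity or specificity.

## Numerical choices and problem sizes

Logistic and Cox fits delegate to `stats::glm` and `survival::coxph`
(Breslow ties, convergence tightened to `eps = 1e-11` so that the two
parameterisations of the interaction model agree to ~1e-10). The exact
binomial test delegates to `stats::binom.test`; the test suite checks it
against an independent combinatorial summation to 12 significant digits
up to depth 500. Table percentages round half away from zero to one
decimal, hazard-ratio displays to three, matching the conventions of
published cohort tables.

The simulation-based checks use: 50,000 participants for the
filter-cascade confusion matrix (the scale at which every recurrent true
hotspot has enough carriers for the age-association test to have power
~1); 50 replicates of 20,000 for Cox parameter recovery (true log-HRs
inside the 95% CI in >= 90% of replicates); 500 replicates of 5,000 for
delta-method RERI coverage under a null generator (nominal 95%, accepted
band 93–97%); and 300 replicates for the recurrence-filter null removal
rate (~81% within three Monte-Carlo standard errors). These sizes were
chosen to make Monte-Carlo noise small relative to the property being
asserted while keeping a full test run in minutes on one core.

## Known limitations

- The packaged whitelist is a representative stand-in, not a curated
  production list.
- mCA detection itself (LRR/BAF segmentation, phasing) is out of scope;
  the package consumes call tables.
- No competing-risks or time-varying-exposure models; CH status is a
  one-time baseline measurement.
- The published tables this package's reference data reproduce contain
  internal inconsistencies in the sex-chromosome interaction blocks
  (printed metrics that do not follow from the printed per-category
  hazard ratios within rounding); the reference table records the
  printed values as-is, and the test suite documents where
  recomputation and print disagree.
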
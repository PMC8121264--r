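---
title: "Intrauterine position analysis of rodent fetal growth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrauterine position analysis of rodent fetal growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Developmental and reproductive toxicology (DART) studies classically evaluate
fetal growth by averaging fetal weight within each litter and then across each
treatment group, comparing groups with a Student's t-test. In multiparous
rodents this discards three known sources of structure: the fetus's anatomical
position within its uterine horn, the number of feti sharing that horn, and
the size of the dam. Perfusion of the bicornuate rodent uterus is not uniform
— each horn is fed cranially by the ovarian artery and caudally by the uterine
artery, and middle positions receive dual supply — so a treatment can restrict
growth at specific positions while litter means barely move. `iupos`
implements a positional analysis pipeline that makes this structure explicit,
together with a synthetic-litter generator so every stage, and the power
contrast between the two analysis routes, can be exercised without animal
data.

## The pipeline

Input is a flat per-fetus necropsy table (dam, group, maternal GD 20 weight,
horn side, fetus index counted from the ovarian end, fetal and placental wet
weights). The stages, in order:

1. **Inclusion criteria.** Litters with fewer than five feti are excluded
   entirely; within retained litters, any horn with fewer than five feti is
   excluded individually. Both are reported per group as `k/N` with the
   number of dams as denominator, and a per-horn log records every decision.
2. **Position collapse.** In a horn of $n \ge 5$ feti, position OE is fetus
   1, NOE fetus 2, CE fetus $n$, NCE fetus $n-1$, and the $n-4$ feti in
   between form the middle (MD), averaged to a single value. The analysis
   unit thereafter is one observation per dam x side x position.
3. **Endpoints.** Normalized fetal weight
   $w^{*} = w \,/\, (M / n_{\mathrm{horn}})$, where $w$ is fetal weight, $M$
   maternal GD 20 weight and $n_{\mathrm{horn}}$ the feti in that horn; raw
   placental weight; and placental efficiency $w / p$ with $p$ the placental
   weight. The traditional route is computed alongside: litter means of raw
   fetal weight, group mean ± SEM, and an integer percent decrease vs
   control.
4. **Outlier screening.** An iterative two-sided Grubbs test
   ($G = \max_i |x_i - \bar{x}| / s$, critical value from the
   $\alpha/(2n)$ t-quantile) applied within each group x side x position
   cell of each endpoint, removing one point per pass.
5. **Inference.** (a) Within each group, a horn side x position two-factor
   ANOVA with Sidak-adjusted contrasts of right vs left at each position;
   (b) for each exposed group and horn side, a group-vs-control x position
   ANOVA with Sidak contrasts per position; (c) Cohen's d for every
   contrast; plus the traditional pooled-variance t-test on litter means.

## Statistical choices

**Type-III sums of squares.** Exclusions and missing placentas leave cell
counts unequal, so the ANOVA computes each term's SS by model comparison
under sum-to-zero coding (drop the term's columns from the full design and
take the residual-SS increase). On balanced data this reduces to the textbook
decomposition — the test suite checks both equivalences against independent
oracles (a hand-coded mean decomposition, and `car::Anova(type = 3)`).

**Sidak family.** Each ANOVA defines one family of five contrasts (the five
positions), adjusted as $p_{\mathrm{adj}} = 1 - (1 - p)^5$. This mirrors the
per-cell comparison convention of the graphing software commonly used for
such studies. Contrast standard errors use the pooled residual MS and its
degrees of freedom.

**Grubbs scope.** Screening is per analysis cell, never pooled across
groups: pooling would let a real treatment effect masquerade as outliers of
the combined sample. Whether to screen once per endpoint or per cell is a
genuinely open choice; the per-cell decision is the package's own and every
removal is logged. Constant cells (sd = 0) and cells with $n < 3$ are left
untouched; ties in the most-deviant point resolve to the first occurrence.

**Independence assumption.** Observations are treated as independent across
positions within a dam — plain two-factor ANOVA, no dam random effect. This
matches the analysis being implemented, but it is a known simplification:
litter effects induce within-dam correlation, and a mixed model with dam as a
random intercept would be the stricter treatment. Such positive within-dam
correlation makes the Sidak family conservative rather than liberal (the
null-calibration test confirms familywise error ≤ 0.06), but single-contrast
p-values should be read with the simplification in mind.

**Rounding conventions.** Percent decrease is
$\mathrm{round}(100(\bar{x}_c - \bar{x}_g)/\bar{x}_c)$ with halves away from
zero, floored at 0 so that a group mean above control prints "0%". Printed
summary tables in the literature are sometimes computed from unrounded group
means; applying this rule to already-rounded means can therefore differ by
one point from a published cell (e.g. means printed as 2.62 and 2.53 give
3.4% → 3%, while the unrounded means may have produced 4%). The package
documents the convention rather than adopting a bespoke rounding to match any
particular printed value.

**Placental endpoints.** A missing placental weight drops that fetus from
placental endpoints only. At the middle position, placental efficiency is
computed per fetus ($w_i/p_i$) and then averaged over the middle feti that
have a placenta, rather than dividing the two middle means: a ratio of means
would silently mix member sets when some placentas are missing.

**Degenerate inputs.** An all-constant ANOVA cell system returns a
"no variance" result with `NA` F and p rather than dividing by zero; empty
cells abort with the cell named; horns below five feti are a hard
precondition error at collapse time so that filtering can never be silently
skipped.

## The synthetic-litter generator

`simulation_config()` fixes the study conditions: 20 control dams (6-9 per
exposed group in the scenarios), maternal GD 20 weight $N(330, 20^2)$ g —
a plausible near-term Sprague-Dawley value, chosen since maternal weights are
rarely reported — per-horn litter sizes uniform on 4..8, baseline fetal
weight 2.62 g with 0.15 g fetus-level noise, placental weight
$N(0.52, 0.05^2)$ g so that efficiency sits near 5, a small right-horn
advantage (multipliers R 1.02 / L 0.98) and an elevated middle position
(MD 1.05), matching the control-condition pattern in which right-horn and
middle feti run slightly heavier. Treatment effects are multiplicative
fractional reductions per (group, side, position) cell, chosen over additive
shifts because reported deficits are proportional across positions of
different baselines. Fetal weights are floored at 0.5 g to exclude
nonphysical draws; placental draws are independent of fetal noise by default
(a correlation knob exists, default 0) because placental weight is typically
unaffected where fetal weight falls.

**Maternal/litter coupling.** Raw fetal weight additionally scales with
$\left(\frac{M/n_{\mathrm{horn}}}{E[M/n_{\mathrm{horn}}]}\right)^{\kappa}$,
a mean-preserving factor making heavier dams and emptier horns produce
heavier feti — exactly the structure the normalization $w/(M/n)$ exists to
remove, and the empirically documented inverse litter-size/weight and
maternal-size/weight relationships. $\kappa = 1$ is the exact proportional
model implied by the normalization; $\kappa = 0$ switches the coupling off.
The default $\kappa = 0.35$ was calibrated so the between-litter SD of
litter-mean weight is ≈ 0.18 g, the dispersion implied by control SEMs near
0.04 g over 20 litters in near-term rat studies; full proportionality would
overstate it about three-fold. The degenerate unit tests (exact 2.62 g
weights) set $\kappa = 0$ together with zero noise and unit multipliers.

**What the generator does not emulate.** No resorptions or group-dependent
litter-size laws (exposure-induced litter shrinkage is a real channel that
couples to the normalization), no fetal sex, no dam-level random intercept
beyond the coupling factor, no within-horn spatial correlation of noise, and
no placental response to treatment. Passing simulation tests therefore show
that the pipeline behaves correctly under its own assumed structure — they do
not certify behaviour under litter effects or resorption patterns the
generator does not produce.

## The power experiments

`power_experiment()` re-simulates the study and pushes each replicate through
both routes, recording the traditional t-test p-value and percent decrease
per exposed group and the Sidak contrast p-values per group x side x
position. Three standing experiments (problem sizes chosen to keep the
default runs to a few minutes):

- **Null calibration** (zero effects, 20 vs 7 dams, 1000 replicates in the
  acceptance suite): familywise Sidak rejection per (group, side) family
  stays at or below the nominal 5% (observed ≈ 0.046-0.051).
- **Broad right-horn deficit** (45% at R OE/NOE/MD/NCE, 6 vs 20 dams, 500
  replicates): both routes reject essentially always. A deficit spanning
  ~80% of one horn moves the litter mean by ≈ 19%, which is far outside the
  traditional test's noise floor — under a shared litter-size law, the
  normalized cell ratio and the raw cell ratio coincide, so a > 40%
  positional gap *forces* a > 15% litter-mean decrease. Masking of an effect
  this broad can only arise through channels the generator deliberately does
  not model (group-dependent litter sizes or maternal weights).
- **Localized deficit** (45% at the right middle only, 300 replicates): the
  masking regime. Litter averaging dilutes the effect to a ~7% decrease and
  ~60% t-test power, while the positional RMD contrast retains essentially
  full power. This is the regime in which positional analysis earns its
  keep: effects concentrated in few positions, invisible after averaging.

Effect recovery closes the loop: over 200 replicates of the broad scenario,
the fraction $1 - \bar{w}^{*}_{\mathrm{exposed,RMD}} /
\bar{w}^{*}_{\mathrm{control,RMD}}$ recovers the configured 0.45 within
Monte-Carlo error, and spared cells recover ≈ 0.

## Known limitations

- No mixed-effects (dam-as-random-effect) alternative; positional
  observations from the same dam are treated as independent.
- Pooling of multiple control arms (e.g. naive and filtered-air) is a
  labelling decision left to the user — the pipeline takes a single control
  label and does not formalise a pooling rule.
- The overall right-vs-left horn comparison is reported as the marginal
  horn-side effect of the within-group ANOVA, with a plain pooled t-test on
  all normalized values as an alternative output; which of the two a given
  published figure used is often ambiguous.
- Normalized fetal weight is reported unitless; the quantity is
  dimensionally grams per (gram per fetus), conventionally printed in "g".
- Fetal sex, crown-rump length and resorption sites are out of scope.
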
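---
title: "Methods: the deR activity score and its surrounding pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the deR activity score and its surrounding pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derscore)
```

## The problem

Nuclear YAP1 (or its paralog TAZ/WWTR1) binds TEAD transcription factors and
drives a proliferative transcriptional program. The Hippo kinase cascade
(NF2 → LATS1/2 and partners) restrains it, and loss of Hippo tumor
suppressors — NF2, LATS2, BAP1, frequent in malignant pleural mesothelioma —
de-represses YAP1-TEAD transcription. Assessing how active this program is
in a given sample, from its transcriptome alone, is useful in three places:
ranking tumor cohorts by pathway activation, linking activation to specific
genetic lesions, and following pharmacodynamic modulation under TEAD or
YAP1 inhibition. `derscore` implements that workflow end to end on data the
user supplies as plain tables, plus simulators that generate cohorts with a
known ground truth.

## The deR score

For one sample, let the measured *effector genes* — a curated set of genes
whose RNA tracks YAP1-TEAD activity positively (set $P$) or negatively
(set $N$) — have abundances $x_g$. The abundances are converted to
*fractional ranks*: ascending ranks with ties assigned the mean of their
integer ranks, divided by the number of measured values, so
$r_g \in (0, 1]$. The score is

$$\mathrm{deR} = R_p - R_n, \qquad
R_p = \frac{1}{|P|}\sum_{g \in P} r_g, \quad
R_n = \frac{1}{|N|}\sum_{g \in N} r_g .$$

deR is the average rank separation between positive and negative effectors.
Because only within-sample ranks enter, the score is invariant under any
strictly increasing transform of a sample's abundances — no normalization
across samples is needed, and mixed units (counts, TPM, array intensities)
are acceptable as long as each sample is internally monotone.

**Rank universe.** By default ranks are computed over the effector genes
only (the effector set is isolated from the transcriptome first). This
bounds deR in $[-0.5, 0.5]$, with a bound attained exactly when every
positive effector exceeds every negative one (or vice versa). An
`"all"`-genes universe is available for sensitivity analysis; it widens the
attainable range and is not the default.

**Ties and missingness.** Ties are exact floating-point equality — no
epsilon snapping — so data rounded upstream may tie deliberately.
Per-sample missing values are dropped before ranking; `n_pos_used` /
`n_neg_used` are reported so coverage is auditable, a matrix-wide coverage
warning fires below 50% of either set, and a sample in which an entire
direction is unmeasured yields an error row rather than a silent number.

## Deriving the signature

The effector sets are derived from a collection of *oriented* perturbation
differential-expression tables: each contrast carries a
`perturbation_sign`, $-1$ when the intervention is expected to lower
YAP1-TEAD activity (YAP1 knockout), $+1$ when it should raise it (Hippo
gene knockout, constitutively active YAP1). For each gene,
`oriented_direction = perturbation_sign × sign(logFC)` maps the observed
change onto the activity axis: a gene falling under a YAP1 knockout is a
positive-effector candidate.

A gene is retained in a direction when it is significant at raw
$p < \alpha$ (default $0.01$) with that oriented direction in at least
`min_support` experiments (default 2). "Consistently" is enforced by the
conflict policy: under `strict` (default) one significant discordant
observation excludes the gene — the most literal reading; `majority`
(concordant > discordant) is provided because the wording of such rules is
genuinely ambiguous. Raw p-values are used deliberately: the retention rule
is itself a replication filter, and adding a per-experiment multiplicity
adjustment would change the stated threshold. Genes absent from a table
contribute neither support nor conflict; a zero effect contributes neither
direction. Each supplied table counts as one experiment — when a published
series contains several contrasts the user chooses the granularity by what
they pass in.

One subtlety worth recording: with a conflict policy in force, enlarging
$\alpha$ is *not* guaranteed to enlarge the sets (a newly significant
discordant observation can evict a gene). Monotonicity holds in
`min_support`, and in $\alpha$ on conflict-free collections; the tests
check exactly that.

## Group statistics

Group comparisons of deR use the two-sided Mann-Whitney rank-sum test —
rank-based, like the score itself — with exact enumeration when both groups
have at most 8 untied observations and the tie-corrected normal
approximation otherwise. Group summaries report the mean with a Student-t
95% confidence interval (matching symmetric "95% confidence limits" error
bars on pharmacodynamic time courses) plus the median; a single-sample
group gets a point estimate with the CI flagged undefined. Cohort rankings
order by mean deR, ties broken lexicographically so output is deterministic.

## Alteration calling and association ranking

A gene is *altered* in a sample iff its GISTIC-style thresholded
copy-number call is $-2$ (deep deletion) or $+2$ (amplification), or it
carries a non-synonymous mutation. Shallow events ($\pm 1$) never qualify.
The non-synonymous classes are the MAF protein-altering set: missense,
nonsense, nonstop, frameshift (ins/del), in-frame indel, splice site,
translation start site; anything else — including unknown strings, which
warn — is treated as synonymous. A cell missing copy-number but covered by
mutation profiling is evaluable through mutations alone; a cell missing
both is excluded from prevalence denominators.

Association ranking tests, per event gene, carriers against a reference
group on deR. Under the `strict` policy the reference is diploid wildtype
(copy-number exactly 0, no known non-synonymous mutation) and
shallow-event samples are excluded from the comparison entirely;
`inclusive` uses all non-carriers. Deletion-type events can be defined as
deep deletion OR mutation (`event_type = "mut_or_del"`, the natural
definition for an NF2-like tumor suppressor), amplification excluded.
P-values are Benjamini-Hochberg adjusted across tested events; ranking is
by ascending p, ties by descending absolute median difference, then gene
name. Events with fewer than 3 carriers or 3 reference samples are skipped
with an explicit reason rather than tested unstably.

## Study arithmetic

Tumor volume from perpendicular caliper diameters is $V = d^2 D / 2$ (mm³),
$d \le D$ enforced — swapped arguments are a usage error, not a silent
reorder. Tumor growth inhibition is defined on mean volume change from
baseline, $100(1 - \overline{\Delta V}_t / \overline{\Delta V}_c)$, with an
endpoint-volume variant by flag; TGI is refused when the control arm itself
regressed, where the quantity is undefined. Regression is per animal,
$100(V_0 - V_1)/V_0$, summarized by the median. Published reports using
these percentages rarely print the formulas; the definitions here are the
package's own, stated so results are reproducible. Relative qPCR
quantification is the comparative-Ct method:
$\Delta C_t = C_t^{target} - C_t^{ref}$ per condition,
$RQ = 2^{-\Delta\Delta C_t}$ against a calibrator, satisfying
$RQ(A,B) \cdot RQ(B,A) = 1$.

## The simulators, and what they do not emulate

All generators are pure functions of (configuration, seed): seeds are
mandatory, runs are bit-identical, and the caller's RNG stream is left
untouched.

`simulate_cohort()` draws a latent per-sample activity
$a_s \sim N(0, 1)$ and sets expression to
$\mu_g + d_g \cdot \beta \cdot a_s + \varepsilon$, with $d_g = \pm 1$ for
planted effectors and 0 for null genes, gene baselines
$\mu_g \sim N(0, 1)$, and noise $\varepsilon \sim N(0, 1)$. Effect sizes
$\beta$ are therefore in within-gene noise-SD units, keeping recovery
thresholds unit-free; the default $\beta = 1$ with 50+50 effectors in 1000
genes and $n = 200$ samples is the reference condition at which deR
recovers the latent activity with Spearman $\rho > 0.9$ (and $|\rho| <
0.15$ when $\beta = 0$). Recovery is insensitive to the baseline spread,
which only reshuffles the within-sample rank frame.

`simulate_experiments()` emulates a perturbation panel: planted effectors
get effects signed as `perturbation_sign × direction` with magnitude
$|N(2, 0.25)|$ and p-values drawn directly as
`planted_p_scale × Beta(0.5, 20)`; null genes get small centered effects
and Uniform(0,1) p-values. Direct p-value simulation keeps the generator
fast and its null exact; "strong planting" (scale $10^{-4}$, used in the
recovery checks) makes every planted observation pass $p < 0.01$ so that
recovery measures the retention logic, not p-value luck.

`simulate_alterations()` draws independent Bernoulli deep-deletion,
amplification and mutation events per gene and sample (deletion wins a
double copy-number draw), then adds each coupled gene's stated activity
shift to carrier samples *before* expression is generated —
`simulate_multiomic_cohort()` enforces that order. The reference coupled
condition is an NF2-like event at +1.5 SD with prevalence 0.3 against 19
null events.

Deliberate simplifications: no negative-binomial count noise or
library-size effects, no tumor purity or clonal structure, no
co-occurrence between alteration events beyond the activity coupling, and
no attempt to match any particular public series' values. Passing the
recovery checks therefore shows the pipeline's logic is correct under its
stated model — not that real cohorts meet that model. On real data the
main risks are effector coverage (hence the coverage bookkeeping) and
cross-species or alias gene-symbol mismatches, which the package
deliberately does not resolve.

## Problem sizes and numerical choices in the checks

The test suite and the acceptance script use: 500 random instances
(≤10 effector genes × ≤8 samples) for oracle agreement at $10^{-12}$;
1000 instances for the bound/antisymmetry properties; 100 for monotone
invariance; the 6-experiment × 1000-gene panel for signature recovery;
$n = 200$ cohorts for activity recovery; 100 replicates for the coupled
association study and 500 for its type-I null (carrier prevalence 0.2,
$n = 60$, expecting the fraction of $p < 0.05$ in $[0.03, 0.08]$). These
sizes give stable verdicts in about a minute of compute; they are the
package's reference conditions, and all are re-derived at run time rather
than stored.

## Known limitations

* deR measures a transcriptional correlate of YAP1-TEAD activity, not YAP1
  protein state or TEAD occupancy.
* Gene identifiers are exact case-sensitive strings; ortholog and alias
  mapping are the user's responsibility before data enter the pipeline.
* The derivation consumes published differential-expression tables as
  given; it does not re-run differential expression, batch-correct, or
  harmonize platforms.
* Survival analysis against the score, copy-number calling from raw data,
  and longitudinal in vivo ANOVA are out of scope; group comparisons route
  through the rank-sum utilities.
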
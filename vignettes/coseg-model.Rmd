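---
title: "The co-segregation likelihood model behind coseglr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The co-segregation likelihood model behind coseglr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coseglr)
```

## The question the model answers

When a variant of uncertain significance (VUS) in *BRCA1*, *BRCA2* or
*PALB2* is found in a cancer family, the pattern in which the variant
tracks with disease among relatives is itself evidence: a pathogenic
variant should be found more often in affected relatives and less often
in unaffected elderly relatives than Mendelian transmission alone would
predict. `coseglr` quantifies that evidence as a likelihood ratio

$$
LR \;=\; \frac{P_d(G_o \mid Ph_f,\, G_p = 1)}
              {P_n(G_o \mid Ph_f,\, G_p = 1)},
$$

the probability of the observed family genotypes $G_o$ given the family
phenotypes $Ph_f$ under the pathogenic hypothesis, divided by the same
probability under the benign hypothesis, both conditional on the proband
being a carrier ($G_p = 1$). An LR of 1 is no evidence; values above 1
support pathogenicity (ACMG/AMP code PP1), values below 1 support a
benign interpretation (BS4). Because it is a Bayes factor, LRs from
independent families carrying the same variant multiply
(`combine_families()`), and the product maps onto evidence-strength
bands via a user-configurable thresholds table (`lr_to_acmg()`).

## Survival formulation of the phenotype likelihood

Each individual's cancer history enters through standard survival
likelihood contributions. For a cancer with age-at-onset distribution
described by penetrance $F(t)$ (cumulative risk by age $t$), survival
$S(t) = 1 - F(t)$, density $f(t) = F'(t)$ and hazard $h(t) = f(t)/S(t)$:

* a person diagnosed at age $t$ contributes $f(t) = h(t)\,S(t)$ — they
  stayed cancer-free until $t$ and were then diagnosed;
* a person cancer-free at their last follow-up (or death) at age $c$
  contributes $S(c)$.

Under the pathogenic hypothesis carriers are scored with carrier curves
and noncarriers with general-population curves; under the benign
hypothesis phenotypes are independent of genotype, so the genotype
probability reduces to pure Mendelian transmission. Individuals with
unknown age are censored at 0 and contribute $S(0) = 1$: they are
retained for the transmission structure but carry no phenotype
information. Death censors (the model is cause-specific: dying
contributes no likelihood term). Males contribute only through
male-applicable cancer processes and are phenotype-uninformative when
there are none.

## The penetrance model

Penetrance curves are smooth parametric functions rather than stepwise
liability classes: a normal distribution of age at onset, truncated at
age 0 and renormalised on $[0,\infty)$, scaled by the lifetime risk $r$:

$$F(t) = r\,F_0(t;\mu,\sigma), \qquad
  f(t) = r\,f_0(t;\mu,\sigma), \qquad
  h(t) = \frac{r f_0(t)}{1 - r F_0(t)},$$

with three interpretable parameters per gene × cancer × sex ×
carrier-status curve: $r$ (lifetime cumulative risk, in $(0,1)$), $\mu$
(mean age at onset, years) and $\sigma$ (spread of onset age, years).
Truncation at 0 (rather than evaluating the untruncated CDF) was chosen
so that $F(0)=0$ holds exactly and $F$ saturates at exactly $r$; for
realistic $(\mu,\sigma)$ the renormalisation constant is within $10^{-4}$
of 1, so this choice is conservative rather than consequential.

`fit_penetrance()` estimates $(r,\mu,\sigma)$ from an age-specific
incidence-rate table by least squares between observed rates $y_i$ and
the model hazard at interval midpoints,
$\sum_i w_i\,\bigl(y_i - h(t_i)\bigr)^2$, with interval-width weights
$w_i$. Midpoints with width weights are unbiased for piecewise-constant
data. Carrier incidence tables are built with `carrier_incidence()` as
population rate × published age-specific relative risk on the refined
grid formed by the union of both tables' interval boundaries; where the
relative-risk table ends, RR defaults to 1, and the smooth fit then
extrapolates beyond the last interval.

Numerical choices for the fit: bounded L-BFGS-B from eight deterministic
starts on a coarse $(r,\mu,\sigma)$ grid (bounds $r \in (10^{-4},
0.999)$, $\mu \in (20, 100)$, $\sigma \in (2, 40)$), the objective
rescaled by $1/\max_i y_i^2$ so its magnitude is $O(1)$ even for rare
cancers (otherwise relative stopping rules fire while absolute residuals
still matter), followed by a derivative-free Nelder–Mead polish. The
multi-start grid is fixed, so fits are reproducible; a parameter pinned
at a bound raises a warning in the result. Noiseless forward-generated
tables (`synth_incidence()`) are recovered to ~$10^{-11}$ relative.

## Contralateral breast cancer

A second primary in the other breast (CBC) is not independent of the
first: the package models it conditionally on the first breast cancer
with a constant hazard $\lambda$ in time since the first diagnosis,

$$f_{cbc}(u) = \lambda e^{-\lambda u}, \qquad
  S_{cbc}(u) = e^{-\lambda u}, \qquad u = t_{cbc} - t_{bc} \ge 0,$$

because conditional CBC incidence shows no clear trend in time since
diagnosis. `fit_cbc()` estimates $\lambda$ as the width-weighted mean of
the conditional rates (the least-squares constant). The conditional
model is applied under both hypotheses with hypothesis-specific rates
(carrier and population $\lambda$), and a BC survivor free of CBC at
censoring contributes the survival complement
$e^{-\lambda(c - t_{bc})}$. A same-age bilateral diagnosis is legal:
$u = 0$ and the density is simply $\lambda$.

The historical formulation, which predates conditional CBC data, treated
the two breasts as independent processes and replaced the first-BC
density by $f(t_{bc})\,f(t_{cbc}) / \bigl(4\sqrt{S(t_{bc})S(t_{cbc})}\bigr)$.
That term is exposed as `legacy_cbc_contribution()` and as the
`legacy_cbc` analysis mode for reproducing older analyses; in that mode
a BC survivor without CBC contributes only $f(t_{bc})$, as the original
model carried no explicit conditional CBC survival factor.

## Three ways to handle multiple cancers

Reliable co-occurrence risks exist for BC + CBC but not for most other
cancer pairs, so the treatment of multi-cancer histories is a user
choice (`mode` of `compute_lr()`):

* **`all_relevant`** — every modelled cancer is an independent process
  run to diagnosis or censoring (CBC via the conditional model). Uses
  all information, at the price of the independence assumption —
  surveillance and treatment after a first cancer in reality modify
  later risks.
* **`first_diagnosis`** — follow-up ends at the first gene-related
  diagnosis: that cancer contributes its density and every other
  process its survival at that age. This mirrors expert-panel (VCEP)
  practice but discards information: a woman with BC *and* OC at young
  ages is stronger evidence than BC alone.
* **`first_diagnosis_plus_cbc`** (default) — the hybrid: censor at the
  first diagnosis except that CBC after a first BC is retained through
  the conditional model, for which good data exist.

When the first diagnosis ties across cancers (same recorded age), each
tied cancer contributes its density and the remaining processes their
survival at that age. Cancers for which the penetrance set carries no
curve for the analysed gene are not gene-associated and are ignored
entirely — they neither contribute nor censor.

## Genotype enumeration and the likelihood ratio

The variant is modelled as rare ($q < 0.01$) and dominant. Founders are
carriers with prior $2q(1-q)$; carriers are treated as heterozygous, and
in transmission a carrier × carrier mating produces a carrier child with
probability $3/4$ (the heterozygote/homozygote distinction is collapsed,
an error of order $q$). Monozygotic twins share one genotype variable
and one transmission term. The default $q = 10^{-4}$ is configurable.

`compute_lr()` enumerates every assignment of carrier status to the
family, exactly (no peeling), in log space and in chunks of at most
$2^{16}$ assignments so memory stays bounded; pedigrees beyond the
configuration cap (default $2^{26}$) raise an error that points to
`trim_pedigree()`. With per-individual log-likelihoods
$\ell_i(\text{carrier})$, $\ell_i(\text{noncarrier})$ the numerator is
obtained by Bayes inversion over configurations $c$ with the proband a
carrier:

$$P_d(G_o \mid Ph, G_p{=}1) =
  \frac{\sum_{c \sim G_o} P(Ph\mid c)\, P(c)}
       {\sum_{c} P(Ph \mid c)\, P(c)},
\qquad
P_n(G_o \mid Ph, G_p{=}1) = \sum_{c \sim G_o} P(c),$$

where $c \sim G_o$ means consistency with all observed genotypes and
$P(c)$ is the Mendelian prior renormalised over proband-carrier
configurations. Two structural consequences are used as tests: if no
relative besides the proband is genotyped the LR is exactly 1, and if
carrier and population curves coincide the LR is exactly 1. The
enumeration is verified against an independent brute-force $2^n$
summation to $10^{-10}$ relative on dozens of random pedigrees.

Consanguineous matings are detected and rejected: enumeration over
inbred configurations would need a prior normalisation that has not been
validated, so the package refuses rather than risk a silently wrong LR.

## Pedigree input conventions

`read_canrisk()` accepts the CanRisk tabular dialect (header beginning
`##CanRisk`): one gene's test-result column is interpreted per analysis
(`P` → carrier, `N` → noncarrier, otherwise untested), results for other
genes are ignored with a warning, risk-factor and pathology columns are
preserved verbatim for round-tripping, a lone named parent gets a
synthesised untested placeholder co-parent of unknown age, and `Age` 0
means unknown (censor at 0, contribution 1). `trim_pedigree()` removes
leaf branches of untested, unaffected members younger than 20 (plus
placeholder spouses orphaned by the removal); such members are nearly
uninformative, and the removal changes the LR by well under 1% in the
bundled checks while shrinking the enumeration.

## Bundled parameter sets are synthetic stand-ins

The files under `inst/extdata/penetrance/` are **synthetic illustrative
parameter sets**, assembled from widely cited literature risk figures
(e.g. carrier lifetime BC risk ≈ 0.72/0.69/0.53 for BRCA1/BRCA2/PALB2,
population lifetime BC risk ≈ 0.12, constant population CBC hazard
≈ 0.004/yr) — they are *not* fits to any national registry and their
provenance fields say so. The `legacy-NL` set mimics the older
high-lifetime-risk parameter era (BRCA1/BRCA2 only, no pancreatic
cancer, no conditional CBC hazard). For clinical use, fit your own
tables with `fit_penetrance()`/`fit_cbc()` and load them via
`load_penetrance_set(source_config = ...)`. Consequently, the package's
example LRs illustrate the machinery; they are not reproductions of any
published analysis.

## What the simulator emulates — and what it does not

`simulate_pedigree()` generates three-generation families (founder
couple, their children with married-in spouses, grandchildren; sibship
sizes Poisson(1.5) truncated at 3 and two generation-2 children by
default, keeping families within the exact-enumeration budget), samples
the genotype configuration *exactly* from the Mendelian prior
conditioned on a carrier proband (by enumeration, not rejection), draws
onset ages by inverse-CDF sampling from the scaled truncated-normal
curves (affected with probability $r$, onset conditional on being ever
affected), CBC waiting times from the exponential conditional model,
uniform censoring ages, and masks genotypes independently at a
configurable rate.

Under its benign model everyone's phenotypes come from population curves
regardless of genotype, which makes the LR a likelihood ratio evaluated
on data drawn from its own denominator model — hence $E[LR] = 1$
exactly, the basis of the null-calibration check (500 replicates must
bracket 1 within 3 Monte-Carlo standard errors; run on the
single-cancer toy set so the martingale argument is transparent and the
check cheap). The simulator does *not* emulate ascertainment bias
(families are not selected for being dramatic), competing mortality,
screening or risk-reducing surgery, birth-cohort effects, or genotyping
error — so passing calibration says the arithmetic is right under the
model's own assumptions, not that the model is right for real families.

## Problem sizes used by the packaged checks

The test-suite and acceptance checks use: 50 random pedigrees of ≤ 10
members for brute-force equivalence, 500 benign-model replicates for
calibration, 50 random $(r,\mu,\sigma)$ triples (drawn from
$r \in (0.02, 0.95)$, $\mu \in (30, 85)$, $\sigma \in (4, 28)$, 5-year
bins 20–90) for parameter recovery, and a 66-point age grid (20–85) for
the smoothness check on the bundled nine-member family. These sizes give
stable Monte-Carlo behaviour while keeping a full run in the order of a
minute.

## Known limitations

* Exact enumeration scales as $2^{\text{free members}}$; very large or
  complex families need trimming. A peeling-style algorithm would lift
  this but is not implemented.
* Pedigrees with loops (consanguinity) are rejected.
* One variant and one gene per analysis; no modelling of multiple
  segregating variants.
* No uncertainty interval accompanies the LR; evidence from few
  informative relatives should be combined across families before
  classification decisions.
* Prostate cancer is deliberately absent: PSA-screen-detected low-risk
  tumours cannot be distinguished in pedigree files and would bias the
  analysis.
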
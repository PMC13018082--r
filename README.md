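# coseglr

Survival-based full-pedigree **co-segregation analysis** for classifying
variants of uncertain significance (VUS) in *BRCA1*, *BRCA2* and
*PALB2*. Given a family pedigree in CanRisk tabular format with cancer
histories and the variant's test results, the package computes the
likelihood ratio

```
LR = P_d(G_o | Ph_f, G_p = 1) / P_n(G_o | Ph_f, G_p = 1)
```

— the probability of the observed family genotypes given the phenotypes
under the pathogenic hypothesis versus the benign hypothesis,
conditional on a carrier proband. LR > 1 supports pathogenicity
(ACMG/AMP PP1), LR < 1 supports benignity (BS4); LRs from independent
families multiply.

The machinery:

* **Smooth penetrance curves** — age at onset is a normal distribution
  truncated at 0 and scaled by the lifetime risk `r`, so `F(t) = r F0(t;
  mu, sigma)`; affected individuals contribute the density `f(t)`,
  unaffected individuals the survival `S(c)` at last follow-up.
  `fit_penetrance()` estimates `(r, mu, sigma)` from 5-year incidence
  tables by least squares on the model hazard
  `h(t) = r f0(t) / (1 - r F0(t))`; `carrier_incidence()` builds carrier
  tables as population rates × age-specific relative risks.
* **Conditional contralateral breast cancer** — constant hazard in time
  since the first breast cancer, `f_cbc(u) = λ e^{-λu}` (`fit_cbc()`),
  applied under both hypotheses; the historical symmetric two-breast
  term is available as a compatibility mode.
* **Three multiple-cancer modes** — treat all gene-related cancers as
  independent processes, censor at the first diagnosis, or the hybrid
  default (censor at first diagnosis but keep CBC).
* **Exact genotype enumeration** — all Mendelian carrier configurations
  of a rare dominant variant (founder prior `2q(1-q)`, default
  `q = 1e-4`), summed in log space; no peeling approximation.

## Worked example

```r
library(coseglr)

ped <- read_canrisk(system.file("extdata", "synthetic_fig1_family.canrisk",
                                package = "coseglr"), gene = "BRCA1")
ped
#> CanRisk pedigree 'FAM1' (9 members, gene BRCA1, proband p)

res <- compute_lr(ped, population = "UK", mode = "first_diagnosis_plus_cbc")
res
#> Co-segregation LR = 6.559
#>   family FAM1 | gene BRCA1 | population UK | mode first_diagnosis_plus_cbc | q = 0.0001
#>   12 consistent / 146 total genotype configurations

lr_to_acmg(res$lr)
#> [1] "PP1_moderate"
```

The family has three breast-cancer cases among tested carriers, one
tested-negative unaffected relative, and an elderly untested relative:
the genotype pattern is ~6.6 times more probable if the variant is
pathogenic, which falls in the "moderate" PP1 evidence band. Per-member
diagnostics come from `tidy(res)`; what-if sweeps over one relative's
age from `lr_by_age()` (plot with `autoplot()`). The same analysis runs
from a shell via the thin CLI in `inst/cli/coseg`:

```sh
inst/cli/coseg run --pedigree family.canrisk --gene BRCA1 \
    --population UK --mode first_diagnosis_plus_cbc --out results/
```

which writes `result.json` and a plain-text `report.txt`.

**Note:** the bundled penetrance sets (and the example pedigree) are
synthetic illustrative stand-ins assembled from widely cited literature
risk figures — not registry fits. Fit your own incidence tables with
`fit_penetrance()` and load them with
`load_penetrance_set(source_config = ...)` for real analyses.

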
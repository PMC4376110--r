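# fallrisk

Fall-risk assessment for community-dwelling adults aged 65+, computed
directly from literature odds ratios — no model fitting on patient data.

About one in three older adults falls at least once a year. Meta-analyses
provide odds ratios for dozens of risk factors, but screening needs a
per-person probability, robust to whatever subset of factors is actually
known. `fallrisk` closes that gap with a noisy-OR causal-independence
model:

- each factor *i* gets a probability contribution
  `C_i = c0 (OR_i − 1) / (1 + c0 (OR_i − 1))`, derived by equating the
  one-exposure odds ratio to the literature value;
- a subject's risk is `P(fall | E) = 1 − (1 − C0) ∏_{i: E_i = 1} (1 − C_i)`;
- unknown exposures are marginalized through their prevalences
  (`1 − p_i C_i`), scalar factors (age, medication count) act through
  nested levels, and synergy factors add risk when two or more members of
  a chronic-disease set co-occur;
- the baseline `C0` is calibrated by bisection so the expected population
  incidence matches the target annual faller proportion (default 31%).

The compiled model can be exported as an equivalent probabilistic logic
program (LPAD, cplint-style syntax), and the package ships a
cohort simulator matching the model's generative assumptions plus a
validation battery (ROC/AUC with DeLong or bootstrap CI, Brier score,
Hosmer–Lemeshow test, decile calibration table).

## Worked example

```r
library(fallrisk)

kb <- default_knowledge_base()   # 27 factors; placeholder OR/prevalence values
m  <- compile_model(kb)          # calibrates C0 to the 0.31 target incidence
m$c0
#> [1] 0.09664717

profile <- subject_profile(
  "history of falls" = "present",
  "gait problems"    = "present",
  "age"              = 3,          # level 3 = 80-84 years under the packaged mapping
  "use of sedatives" = "present",
  "vision impairment" = "unknown"  # unmentioned factors are unknown too
)
fall_risk(m, profile)
#> Fall risk: 0.4547 (baseline C0 = 0.0966)
#> Risk-increasing multipliers:
#>   history of falls                     0.853923
#>   gait problems                        0.907074
#>   use of sedatives                     0.964575
#>   age                                  0.965999
#>   ...
```

The subject's one-year fall probability is 0.455: the baseline 0.097 that
every subject carries, pushed up by the present factors (each line is the
survival multiplier `1 − C` it contributes) and, more weakly, by every
unknown factor at its population prevalence. Setting a factor to
`"absent"` removes its multiplier entirely.

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/cli/fallrisk`): `assess`, `calibrate`, `generate-lpad`, `simulate`
and `validate` subcommands with `--kb`, `--seed`, `--out` flags.

Note: the odds-ratio and prevalence *values* in the packaged knowledge
base are editable placeholders in realistic ranges (marked as such in the
file); replace them with values transcribed from a quantitative source
before substantive use. Structure, kinds and member sets are exact.

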
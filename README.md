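# caretactics

Demographic analysis of alternative maternal-care tactics in a hunted
brown-bear population.

In the Scandinavian brown bear, females wean their litters after either
1.5 or 2.5 years, and hunting regulation protects family groups: a mother
with dependent cubs or yearlings may not be shot. A female using the
2.5-year tactic is therefore legally exposed to hunting in only one year of
three, while a 1.5-year female is exposed every second year — and her
yearlings are exposed too. `caretactics` implements the full analysis chain
needed to ask whether this regulation shifts the fitness balance between
the two tactics:

1. **Records** — a validated tabular data model for individual-based
   monitoring data: bear-years (one female in one hunting-season year) and
   litters (one reproductive event with its realized care duration).
2. **Tactic analysis** — classification of females by mean care duration
   (`>= 2` years → 2.5-year tactic), the annual trend in the odds that a
   litter receives 2.5 years of care (binomial GLMM with female random
   intercept), GLMM-based repeatability of the binary care trait on latent
   and original scales, and primiparity/age correlates.
3. **Demographic rates** — tactic- and age-class-specific survival
   (logistic mixed model, `survival ~ tactic + age_class + (1|year)`) and
   recruitment of yearling daughters (negative-binomial mixed model,
   `recruits ~ tactic + (1|female) + (1|year)`), with parametric-bootstrap
   rate tables and the protective effect of family-group status.
4. **Matrix demography** — the two 9×9 female-based Leslie matrices

   with first row `(0, 0, 0, F₄₋₈, F₄₋₈, F₄₋₈, F₄₋₈, F₄₋₈, F₉₊)`,
   subdiagonal `(S₁, S₂, S₃, S₄₋₈, S₄₋₈, S₄₋₈, S₄₋₈, S₄₋₈)` and a 9+
   self-loop `S₉₊`, where fecundity is `F = S × R` (survive the year, then
   recruit yearling daughters). From each matrix: the asymptotic growth
   rate λ (dominant eigenvalue), the net reproductive rate
   `R₀ = dominant eigenvalue of F(I−U)⁻¹`, generation time
   `T = ln(R₀)/ln(λ)`, the stable age structure, elasticities, and
   bootstrap distributions of all of these with the probability that the
   2.5-year tactic has the longer generation time.
5. **Hunting response** — the annual hunting-pressure index (marked bears
   shot ÷ marked bears available), per tactic × age-class logistic models
   of survival against pressure, and λ as a function of pressure with
   recruitment held fixed.
6. **Simulator** — an individual-based annual-cycle generator whose
   defaults emulate the study population's rate magnitudes, protection
   rule, tactic consistency and temporal trend, so the whole pipeline is
   testable without the (non-public) field data.

## Worked example

```r
library(caretactics)

# Mean rates of the study population: survival per age class
# (1, 2, 3, 4-8, 9+) and yearling-daughter recruitment, per tactic.
A15 <- build_leslie(0.809, 0.844, 0.916, 0.973, 0.841, 0.384, tactic = "T15")
A25 <- build_leslie(0.903, 0.922, 0.961, 0.988, 0.920, 0.251, tactic = "T25")
demography_summary(A15)
#> Demography (T15): lambda = 1.093, R0 = 2.215, T = 8.93 y, adults = 57.2%
demography_summary(A25)
#> Demography (T25): lambda = 1.100, R0 = 3.143, T = 11.96 y, adults = 64.6%
```

Despite a 34.6% lower recruitment, the 2.5-year tactic reaches the same
asymptotic growth (λ 1.10 vs 1.09) because its survival gain weighs more
in a long-lived species; its population would however have a ~3-year
longer generation time and a larger adult fraction.

A full synthetic run, from simulation to the pressure curves:

```r
m <- run_pipeline(pipeline_config(out_dir = "out", seed = 42))
pipeline_report(m)
```

This writes `bear_years.csv`, `litters.csv`, `tactics.json`, `rates.json`,
`demography.json`, `curves.json` and a `manifest.json` with seeds and
checksums; re-running the same configuration reproduces the files
byte-for-byte.

## Data formats

`bear_years.csv`: `bear_id, year, age, tactic, status, survived,
cause_of_death, available_for_hunting, recruits` — e.g.

```csv
bear_id,year,age,tactic,status,survived,cause_of_death,available_for_hunting,recruits
F0007,2001,6,T25,with_offspring,true,none,false,0
F0012,2001,2,T15,solitary,false,hunting,true,
```

`litters.csv`: `litter_id, mother_id, birth_year, weaning_year,
care_duration, litter_size, mother_primiparous` — e.g.

```csv
litter_id,mother_id,birth_year,weaning_year,care_duration,litter_size,mother_primiparous
L0001,F0007,1998,2000,2.5,3,false
L0002,F0012,1999,,lost,2,true
```

Booleans are `true`/`false`, missing values are empty fields, and
`unknown`/`lost` are explicit tokens. Validation is total: every invariant
of the data model (cause-of-death consistency, the legal-protection rule,
care-duration/weaning-year arithmetic, count ranges) is checked on read,
with offending rows reported.

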
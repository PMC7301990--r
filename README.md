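# mgliqual

Service-quality evaluation from **multi-granularity linguistic information
(MGLI)**: raters answer on verbal scales of their own preferred length (a
5-term "fail … excellent" scale, a 7-term "very poor … very good" scale, …),
possibly hesitating between adjacent terms, and the package turns those
answers into a screened evaluation index system and a perception–expectation
(SERVQUAL/5GAP) gap analysis.

It was built around a teleconsultation case study — regional doctors rating
the service quality of a provincial telemedicine platform — whose published
summary tables ship as fixtures, but every step is generic: any indicator
hierarchy, any term-set granularities, any survey.

## The method

A term set `S = {S_0, …, S_T}` is an ordered scale with negation
`Neg(S_t) = S_{T−t}`. A point answer `S_m` or hesitant interval `[S_m, S_n]`
is encoded as a normalized **trapezoidal fuzzy number** `(a, b, c, d)` on
[0, 1]:

```
A = ( max{(2m−1)/(2T+1), 0},  2m/(2T+1),  (2n+1)/(2T+1),  min{(2n+2)/(2T+1), 1} )
```

Because each value is encoded with its *own* scale's `T`, ratings from
different granularities become commensurable and average freely
(componentwise). Crisp summaries use the segmentation-integral
defuzzification `P(A) = (a + 2b + 2c + d)/6`.

The pipeline has three stages:

1. **Aggregate** — expert importance panels are averaged per indicator
   (`expert_mean()`, weighted componentwise mean of encodings); respondent
   surveys yield average perception (AP) and expectation (AE) trapezoids
   per indicator (`survey_means()`).
2. **Screen** — each aggregated importance trapezoid `f*` is compared with
   every reference term encoding `M_θ` by the similarity degree
   `Y(f*, M_θ) = 1 − ¼ Σ_h |f*_h − M_θ^h|`; the zone of the most similar
   term decides *keep* (upper zone), *remove* (lower zone) or *review*
   (middle), and a declarative merge plan integrates reviewed indicators
   into an optimized hierarchy (`screen_indicators()`, `apply_merge_plan()`).
3. **Evaluate** — per indicator, `P = defuzzify(AP)`, `E = defuzzify(AE)`,
   `gap = P − E`; dimensions roll up as unweighted componentwise means of
   their sub-indicators; the most negative gaps are the key factors to
   improve (`indicator_gaps()`, `dimension_rollup()`, `rank_key_factors()`).

A synthetic questionnaire generator (`simulation_spec()`,
`generate_expert_panel()`, `generate_survey()`) plants true levels with
ordinal noise and hesitant-interval answers so the whole pipeline is
testable end to end without the original raw questionnaires.

## Worked example

Screen the bundled case-study expert panel (24 indicators averaged over 15
equally weighted experts) against the 7-term importance scale:

```r
library(mgliqual)

t3  <- load_fixture("table3_expert_trapezoids")
avg <- as.matrix(t3[, c("a", "b", "c", "d")]); rownames(avg) <- t3$indicator_id
scr <- screen_indicators(avg, default_termsets()$seven_importance)
head(format_screening(scr, default_termsets()$seven_importance)[,
     c("indicator_id", "Y2", "Y3", "Y4", "argmax_label", "decision")])
#>               indicator_id     Y2     Y3     Y4         argmax_label decision
#> 1 network_service_provider 0.9642 0.8663 0.7124 slightly unimportant   remove
#> 2             network_rate 0.6862 0.8400 0.9764   slightly important     keep
#> 3         video_resolution 0.5887 0.7425 0.8963            important     keep
#> 4        equipment_quality 0.5579 0.7118 0.8656            important     keep
#> 5      process_convenience 0.7917 0.9455 0.9007               middle   review
#> 6  operational_ease_of_use 0.8117 0.9655 0.8807               middle   review
```

Two indicators sit closest to the unimportant zone and are removed; applying
the case study's merge plan turns the 24-indicator / 5-dimension system into
19 indicators in 4 dimensions:

```r
opt <- apply_merge_plan(load_fixture("initial_hierarchy"), scr,
                        load_fixture("htcc_merge_plan"))
nrow(opt$indicators); nrow(opt$dimensions)
#> [1] 19
#> [1] 4
```

Rank the key factors from the published sub-indicator AP/AE tuples:

```r
t6   <- load_fixture("table6_subindicators")
rep6 <- gap_report(as.matrix(t6[, 5:8]), as.matrix(t6[, 9:12]),
                   ids = t6$indicator_code, names = t6$name)
rank_key_factors(rep6, 5)
#>    id                              name gap_reported         gap
#> 1 C22 Turnover Rates of Consulting Room       -0.031 -0.03050000
#> 2 C37               Operators' Attitude       -0.031 -0.03100000
#> 3 C39             Consultation Duration       -0.029 -0.02866667
#> 4 C23                           Charges       -0.026 -0.02550000
#> 5 C38                 Experts' Attitude       -0.025 -0.02500000
```

Perception falls furthest below expectation for consulting-room turnover,
operator attitude, consultation duration, charges and expert attitude —
the factors most in need of improvement.

A thin CLI wraps the same functions
(`inst/cli/mgliqual {screen|evaluate|simulate}`), reading/writing plain CSV
and JSON.

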
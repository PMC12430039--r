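# sleepdmpm

Bayesian dynamic multivariate panel models and interquartile
do-intervention contrasts for short sleep-diary panels.

## The problem

Sleep diaries record, for each subject and day, three proxies of sleep
quality — daytime sleepiness (`y1`, binary), ease of falling asleep (`y2`,
3-level, 3 = best) and ease of waking up (`y3`, 3-level) — together with
35 covariates in six factor categories: stress (6 four-point items),
bedtime conditions (bedtime relative to midnight, time in bed, pre-bed
caffeine/alcohol/ICT use), weather (5 daily variables shared across
subjects), physical attributes (age, BMI, systolic blood pressure),
exercise habits (4 any-activity dummies) and dietary habits (12 food-group
densities in g per 1000 kcal). The package answers a comparative causal
question: **by how much would each factor category move the outcome
probabilities if its items were improved by one interquartile range?**

## The model and the contrast

The three outcomes form a cross-lagged system ordered within each
waking-to-waking cycle as `y3 -> y1 -> y2`. Each channel is a GLM —
Bernoulli-logit for `y1`, cumulative (proportional-odds) logit for `y2`
and `y3` — whose linear predictor contains lagged/same-day outcome terms
and the 35 covariates at channel-specific lags. Day 1 is the initial
condition; estimation is Hamiltonian Monte Carlo with weakly informative
priors (Normal(0, 2.5) slopes, Normal(0, 5) intercepts/cutpoints).

For a category A and outcome level `y = l`, the improvement metric is

    Delta_A = sum_{k in A} | Pr(y=l | do(x_k = Q1_k), x_-k)
                           - Pr(y=l | do(x_k = Q3_k), x_-k) |

evaluated per posterior draw by simulating the whole panel forward from
each subject's day-1 outcomes under both endpoint policies (common random
numbers), averaging over subjects and days 2..T. A rare binary item whose
interquartile range collapses (pre-bed caffeine) uses the full (0, 1)
move; an "AR(1)" row reports the effect of clamping the previous day's
outcome vector to its best versus worst configuration. Results are
posterior-predictive means with equal-tailed 90% credibility intervals.

Because the study's diary data are access-controlled, the package includes
a synthetic-panel generator (`generate_panel()`) with documented ground
truth — including feedback from yesterday's outcomes into today's stress
items and season-dependent shared weather — so every stage is testable
offline, plus an exhaustive-enumeration oracle (`exact_contrast()`) that
verifies the Monte-Carlo contrast on tiny instances.

## Worked example

```r
library(sleepdmpm)
library(dplyr)

sim <- generate_panel(generator_config(n_subjects = 200, n_days = 6,
                                       seed = 42,
                                       subsamples = "male-summer"))
fit <- fit_dmpm(sim$panel, chains = 4, warmup = 500, iter = 500, seed = 42)
fit
#> <dmpm_fit> 4 chains x 500 draws (+500 warmup), 125 parameters
#>   subjects: 200; observations/channel: 1000/1000/1000
#>   mean acceptance 0.95; divergences 134; max R-hat 1.017

tidy(fit) |>
  filter(channel == "y1",
         term %in% c("bedtime_hr", "caffeine", "time_in_bed_hr")) |>
  select(parameter, estimate, conf.low, conf.high, rhat)
#>   parameter         estimate conf.low conf.high  rhat
#> 1 y1:bedtime_hr       0.0652  -0.0526    0.186   1.00
#> 2 y1:time_in_bed_hr  -0.131   -0.282     0.0231  1.01
#> 3 y1:caffeine        -0.0820  -0.425     0.243   1.00

res <- sleep_contrast(fit, sim$panel, n_rep = 20, seed = 42,
                      draw_ids = round(seq(1, 2000, length.out = 50)))
tidy(res) |> filter(outcome == "y1=1")
#>   category outcome   mean ci_low ci_high
#> 1 stress   y1=1    0.189  0.102    0.251
#> 2 bedtime  y1=1    0.229  0.147    0.300
#> 3 weather  y1=1    0.447  0.139    0.775
#> 4 physical y1=1    0.0773 0.0320   0.129
#> 5 exercise y1=1    0.217  0.121    0.309
#> 6 dietary  y1=1    0.342  0.250    0.431
#> 7 ar1      y1=1    0.302  0.236    0.378
```

Reading the output: the per-parameter rows are posterior means and 90%
intervals of the regression coefficients (per unit of the covariate, on
the logit scale). The contrast table says, e.g., that improving all five
bedtime conditions across their interquartile ranges changes the
probability of a sleepy day by 0.229 in posterior-predictive mean (90%
interval 0.147–0.300), and that serial dependence (AR(1)) contributes
0.302. Note that category sums add *absolute* per-item changes, so items
whose coefficient posterior straddles zero still contribute rectified
noise — e.g. per item in the bedtime category:

```r
res$items |>
  filter(outcome == "y1=1", item %in%
           c("bedtime_hr", "time_in_bed_hr", "caffeine", "alcohol", "ict")) |>
  group_by(item) |>
  summarise(mean = mean(delta), ci_low = quantile(delta, .05),
            ci_high = quantile(delta, .95))
#>   item             mean  ci_low ci_high
#> 1 alcohol        0.0797 0.0345   0.131
#> 2 bedtime_hr     0.0291 0.00381  0.0655
#> 3 caffeine       0.0396 0.00500  0.0824
#> 4 ict            0.0514 0.00952  0.0958
#> 5 time_in_bed_hr 0.0292 0.00512  0.0618
```

Here `bedtime_hr` and `time_in_bed_hr` (truly non-zero in the generator) show
means close to their true interquartile effects (~0.03), while `alcohol`
and `ict` (null in this channel) contribute only rectified posterior
noise; see the methods vignette for this property of the metric.

`run_pipeline(run_config(...))` chains simulate → fit → contrast → report
per gender-season subsample, writing CSV/JSON artifacts and a manifest
with seeds and file hashes; reruns with the same configuration are
byte-identical. `autoplot()` on a contrast result draws the forest-style
category summary.

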
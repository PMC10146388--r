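# riskamp

Social-media conversations can amplify or dampen risk signals, and the
emotional valence of that conversation may move real-world health
behaviour. `riskamp` implements a complete, tested pipeline for studying
that question at the scale of a national Twitter-style conversation and a
daily vaccine-acceptance survey:

1. **Sentinel selection** — build a weighted directed retweet network
   (arc *j → i* = times *j* retweeted *i*), detect communities on the
   largest weakly connected component by directed-modularity Louvain,
   pick the most-retweeted accounts per community (50 at the seed stage,
   80 at the final stage), and widen the set by snowball expansion over
   each seed's most recent 3200 phrase-matching tweets.
2. **Topic modelling** — collapsed-Gibbs LDA (defaults K = 65, α = 0.1)
   with the four standard topic-count selection metrics
   (harmonic-mean likelihood; mean pairwise cosine; singular-value vs
   topic-proportion symmetric KL; mean pairwise Jensen–Shannon), and
   daily topic-cluster prominence from the per-tweet γ scores.
3. **Emotion scoring** — NRC-style lexicon counts per tweet (ten 0/1
   categories), net sentiment = positive − negative, each score weighted
   by the tweet's topic-cluster probability and aggregated per day.
4. **Time-series analysis** — augmented Dickey–Fuller stationarity test
   (MacKinnon response-surface critical values), per-measure bivariate
   VAR(p) with constant and linear trend (default p = 4), orthogonalized
   impulse-response functions with seeded bootstrap bands, and a
   reverse-causality robustness check.

The core model is the bivariate VAR

```
acceptance_t = c + d·t + Σ_{ℓ=1..p} a_ℓ·acceptance_{t−ℓ}
                       + Σ_{ℓ=1..p} b_ℓ·sentiment_{t−ℓ} + u_t
```

whose lag-1 cross-coefficient `b_1` and the horizon-1 orthogonalized IRF
(response of acceptance to a one-standard-deviation sentiment shock)
quantify the *next-day* association between expressed emotion and
acceptance.

A first-class synthetic-data generator (`synth_config()`,
`simulate_study()`) produces every pipeline input — a planted-community
retweet graph with hub accounts, daily token streams mixing planted
Dirichlet topics with lexicon-tagged emotion words, and an acceptance
series from a known autoregression — together with its ground truth, so
every stage is tested by recovery.

## Worked example

```r
library(riskamp)

cfg   <- synth_config(seed = 42)        # the default synthetic study
study <- simulate_study(cfg)

study$graph
#> <retweet_network> 60 nodes, 1841 arcs, total weight m = 4958

louvain_partition(study$graph, seed = 42)
#> <community_partition> 3 communities over 60 nodes, Q = 0.4879

study$acceptance
#> <daily_series> 'acceptance': 231 days (2020-12-21 to 2021-08-08), 0 missing, mean 0.7318

Y   <- cbind(sentiment  = study$truth$driving_signal$value,
             acceptance = study$acceptance$value)
fit <- fit_var(Y, p = 4)
fit
#> VAR(4) with const+trend, variables: sentiment, acceptance, nobs = 227
#>   R2: sentiment = 0.898, acceptance = 0.964; log-likelihood: 1761.97

head(var_coef_table(fit, "acceptance"), 2)
#>            term  estimate         se  ci_lower  ci_upper       pvalue
#> 1  sentiment.l1 0.9053310 0.25842523 0.3988269 1.4118352 5.580388e-04
#> 2 acceptance.l1 0.5591691 0.06795912 0.4259717 0.6923665 1.752877e-14

ir <- irf(fit, H = 10, n_boot = 500, seed = 42)
irf_table(ir, "sentiment", "acceptance")[2, ]
#>   horizon   response       lower       upper
#> 1       1 0.00281932 0.001327023 0.004276853
```

Reading the output: the three planted communities are recovered
(modularity Q ≈ 0.49 on the 60-account graph); the fitted lag-1 sentiment
coefficient is positive and significant (its confidence interval excludes
zero), and a one-standard-deviation sentiment shock raises acceptance by
about 0.0028 on the 0–1 scale the following day, with the bootstrap band
excluding zero — the planted next-day effect, recovered end to end.

The whole pipeline, from simulation through the IRF tables, runs from one
config:

```r
cfg <- pipeline_config(out_dir = "run1", synth = synth_config(seed = 1), seed = 1)
manifest <- run_pipeline(cfg)   # writes stage artifacts + manifest.json
make_report("run1")             # timeline + IRF figures, coefficient tables
```

A thin command-line wrapper is installed at `inst/cli/riskamp.R`
(`riskamp.R run --out DIR --seed 1`, `riskamp.R report --out DIR`).

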
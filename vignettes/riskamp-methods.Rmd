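---
title: "Methods: sentinel surveillance, topic-weighted emotion, and next-day effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sentinel surveillance, topic-weighted emotion, and next-day effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`riskamp` implements a four-stage infodemiology pipeline for linking
social-media discourse about vaccination to a daily vaccine-acceptance
survey series, together with a synthetic-data generator whose ground truth
makes every stage testable by recovery. This vignette is the package's own
account of the methods: the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic experiments do
and do not demonstrate.

## Stage 1 — sentinel account selection on retweet networks

Platform-wide surveillance of a national conversation is infeasible; the
pipeline instead monitors a small set of *sentinel* accounts chosen by
network position. From phrase-filtered tweet records (default phrases:
`covid`, `coronavirus`, `pandemia`, `vacuna`; case-insensitive substring
match, token-exact mode available) it builds a weighted directed retweet
network in which the arc $j \to i$ carries the number of times account $j$
retweeted account $i$.

Communities are found on the largest *weakly* connected component by
maximizing directed modularity

$$Q = \frac{1}{m}\sum_{ij}\left[A_{ij} -
  \frac{k_i^{\mathrm{out}} k_j^{\mathrm{in}}}{m}\right]\delta(c_i, c_j),$$

with $m$ the total arc weight and $k^{\mathrm{out}}, k^{\mathrm{in}}$ the
node strengths, via a Louvain scheme (greedy local moving plus graph
aggregation) adapted to directed graphs. Three choices here are genuinely
open and are fixed as follows, for reproducibility rather than by
necessity:

* **Node visit order** is a seeded shuffle; a node moves to the candidate
  community with the largest strictly positive modularity gain, ties
  broken toward the smallest community label. Fixed seed implies
  bit-identical partitions.
* **Connectivity** is weak (direction ignored): strong connectivity would
  discard most of a retweet graph, which is nearly a DAG.
* **"Most highly retweeted"** is read as largest weighted in-strength, the
  natural dual of the arc-weight semantics, not as a raw record count.

Selection then takes the top-$k$ accounts by in-strength per community
(seed stage $k = 50$, final stage $k = 80$; ties to the smaller account
id, communities smaller than $k$ contribute all members), and
`snowball_expand()` widens the seed set: the most recent 3200 tweets per
seed (recency by day then id), phrase-filtered, rebuilt into a retweet
network, re-partitioned, re-selected, and unioned with the seeds. Community
labels are *permanent*: an account keeps its first-assigned label through
every later stage. Human curation of communities (dropping obviously
irrelevant ones) is replaced by configuration — no interactive step runs at
test time.

## Stage 2 — topics and prominence

Documents (tweets) are preprocessed by lowercasing, stopword removal, a
document-frequency floor, and removal of emptied documents (counted and
reported). Latent Dirichlet allocation is fitted by **collapsed Gibbs
sampling**, resampling each token's topic from

$$p(z = k \mid \cdot) \propto (n_{dk} + \alpha)\,
  \frac{n_{kw} + \beta}{n_{k\cdot} + V\beta}.$$

Gibbs (rather than variational inference) was chosen because its
finite-state posterior can be enumerated exactly on tiny corpora, giving a
sharp correctness oracle: on a 2-document, 6-token, $K=2$ corpus the
sampler's empirical distribution over all 64 assignment vectors is compared
to the enumerated posterior in total variation. Defaults follow common
practice for short texts: $\alpha = 0.1$ (the analysis default),
$\beta = 0.01$, 1000 sweeps with 200 burn-in for production fits (tests and
the bundled pipeline use shorter chains on smaller corpora; chain lengths
are stated in each call). `phi` and `gamma` are posterior means over
post-burn-in sweeps, so both are strictly positive and row-stochastic to
numerical precision.

Topic-count selection reports four standard metrics per fitted $K$:
harmonic-mean marginal likelihood (maximize), mean pairwise cosine between
topic-word rows (minimize), symmetric KL between the normalized singular
values of `phi` and the length-weighted topic proportions (minimize), and
mean pairwise Jensen–Shannon divergence, natural-log convention (maximize).
`preferred_k()` takes a majority vote of the four arg-optima. For $K = 1$
the two pairwise metrics are undefined and reported as missing.

The collapsing of fitted topics into named clusters is inherently a human,
interpretive step; the package carries it as configuration
(`cluster_map()`), including an explicit boilerplate set excluded from
every analysis. The criterion for "boilerplate" is not inferred.

Daily cluster prominence sums each tweet's `gamma` over the cluster's
topics and aggregates per calendar day. Aggregation is **mean** by default:
a per-tweet average keeps the series on the probability scale and does not
grow with daily posting volume; `sum` is implemented behind the same switch
for volume-sensitive analyses. Days with no tweets are *missing*, never
zero.

## Stage 3 — lexicon emotion scoring and topic weighting

Scoring uses an NRC-style lexicon: a word table with 0/1 flags over ten
categories (positive, negative, trust, anger, fear, joy, sadness,
surprise, anticipation, disgust); a word may carry several flags. A
tweet's category count is the number of token occurrences carrying that
flag (repetition counts repeatedly; unknown words contribute nothing), and
net sentiment is exactly positive minus negative. Negation, intensifiers,
emoji, and context are deliberately not modeled — the scores describe the
emotion *of the text*, not sentiment toward a target. Scores are not
normalized by token length by default (counts are the measure; a
normalizing variant is a one-line wrapper on the per-tweet table).

The stage's central quantity is the **topic-weighted score**: the tweet's
net-sentiment (or trust) count multiplied by its topic-cluster
probability, i.e. its summed `gamma` over the cluster — bilinear in both
arguments, zero whenever the tweet is off-cluster. Daily aggregation
follows the same mean/sum switch and missing-day convention as
prominence.

## Stage 4 — stationarity, VAR, impulse responses

The acceptance survey series lives on the $[0, 1]$ scale (fraction of
respondents vaccinated, scheduled, or willing). Before modelling, series
are aligned on their common calendar; interior missing survey days are
linearly interpolated with a warning (a drop-day mode exists). An
augmented Dickey–Fuller regression

$$\Delta y_t = \rho\, y_{t-1} + \textstyle\sum_{j=1}^{L} \phi_j \Delta y_{t-j}
  + \text{deterministics} + \varepsilon_t$$

tests for a unit root; $L$ is chosen by information criterion on a common
sample (Schwert-rule cap by default) and the $t$-ratio of $\rho$ is
compared to MacKinnon (2010) response-surface critical values (a published
table embedded as a constant). The suite verifies empirical size within
[0.03, 0.07] at the nominal 5% level under a pure random walk and power
above 0.95 against an AR(1) with coefficient 0.5 at $n = 500$.

Each sentiment measure is modelled in its own **bivariate VAR** with the
acceptance series — one independent variable per model, eliminating
multicollinearity between collinear sentiment measures. Equation-wise OLS
uses lags $1..p$ of both variables plus a constant and a linear trend
(default $p = 4$; lag selection by AIC/BIC/HQ on a common sample is also
implemented). Conventions that matter for reported numbers and are
therefore fixed explicitly:

* `Sigma_u`, coefficient standard errors, and $R^2_{\text{adj}}$ all use
  the degrees-of-freedom correction $n_{\text{obs}} - n_{\text{params}}$;
  the Gaussian log-likelihood uses the ML covariance.
* Orthogonalized IRFs use the Cholesky factor of `Sigma_u` with the
  **sentiment variable first** in the default ordering — the shock donor
  precedes the responder, matching the directional hypothesis; the
  ordering is an explicit argument.
* IRF bands come from a seeded recursive residual bootstrap (centered
  residuals resampled with replacement, sample regenerated from the
  fitted coefficients and deterministic terms, percentile bands). In the
  rare event a percentile band does not bracket the point estimate, the
  band is widened to include it, preserving the container invariant.
  Unstable fits (companion spectral radius $\ge 1$) still yield the point
  IRF, but bands are refused with a message.
* The reverse-causality robustness check refits the identical machinery
  with the roles swapped and reports per-lag $t$ statistics of the
  acceptance lags in the sentiment equation; swapping twice reproduces
  the original fit bit-for-bit.

## The synthetic study generator

`synth_config()` declares the full data-generating process; its defaults
are the package's standing description of the emulated study design, not
tuning knobs:

* **Retweet graph**: 3 communities of 20 accounts, per-ordered-pair arc
  weights Binomial(10, $p$) with $p_{\text{in}} = 0.3$,
  $p_{\text{out}} = 0.03$ (a 10:1 contrast), 2 hub accounts per community
  whose in-probability is tripled (capped at 1). Binomial pair sampling
  yields integer weights matching the arc semantics exactly.
* **Corpus**: 231 days from 2020-12-21 (the emulated observation window),
  40 posts/day of 12 tokens (the short-text regime), $K = 3$ planted
  topics over a 150-word vocabulary; topic $k$ holds 95% of its mass
  uniformly on its own vocabulary block. Topic 1 is the vaccination topic
  by convention, its block named after the search phrases so the phrase
  filter naturally retains vaccination content. Tweets-per-author are
  uniform — a modelling choice, as the true per-account posting
  distribution is unknown. Posts are retweets with probability 0.3,
  directed along the planted graph's arcs.
* **Emotion signal**: each lexicon category tags 20% of the vocabulary;
  inside the vaccination block a designated positive+trust word set and a
  disjoint negative set are planted. On good-news days (every third day)
  vaccination-topic tokens are swapped for positive/trust words with
  probability 0.5; on bad-news days (interleaved) for negative words.
  The realized daily mean of net-sentiment × vaccination-topic weight is
  the generator's known signal.
* **Acceptance**: generated by the recursion
  $y_t = c + d\,t + \sum_\ell a_\ell y_{t-\ell} + \sum_\ell b_\ell s_{t-\ell}
  + \varepsilon_t$ with $a_1 = 0.6$, $b_1 = 0.5$, $c = 0.25$,
  $d = 0.0003$, $\varepsilon_t \sim N(0, 0.01^2)$ — a stationary,
  trend-bearing process with a positive next-day sentiment effect, the
  qualitative shape of the study design. Stationarity of the $a$
  coefficients is validated up front (companion spectral radius < 1).
  Before entering the recursion the realized signal is standardized to
  mean 0.018, sd 0.008 — the scale of the daily topic-weighted sentiment
  measure — which keeps the series inside $[0, 1]$ without clipping;
  clipping, if a configuration ever forces it, is counted and warned
  about rather than silent. Pre-sample values sit at the deterministic
  steady state with the first sentiment value carried back, keeping the
  recursion local in its inputs.

Every generator function derives its random stream from the single config
seed, so one config reproduces one dataset bit-for-bit.

**What passing tests show — and what they do not.** The generator plants
clean block communities, near-disjoint topics, and a correctly specified
linear acceptance process. Recovery under these conditions demonstrates
that the estimators are implemented correctly and calibrated (coverage,
size, power) at the design scale of 231 daily observations; it does not
certify performance on real platform data, where communities overlap,
topics share vocabulary, lexicons miss slang and emoji, and the acceptance
process is neither linear nor exogenous. The package's claims about real
data end at the method definitions.

## Problem sizes and runtime choices

Test and pipeline runs use deliberately compact instances chosen to
exercise every code path at full statistical strength: 60-node graphs for
community recovery (50 seeded replicates), 500-tweet corpora for topic
recovery, 64-state enumeration for the sampler check, 1000 replicates of
$n = 500$ for ADF size, 200 replicates at $n = 231$, $p = 4$ for VAR
coverage, and 50 replicates with 300 bootstrap draws for IRF detection.
The bundled end-to-end pipeline default in tests runs 100–120 days at 15–20
posts/day with short Gibbs chains; all sizes are ordinary function
arguments and scale up unchanged.

## Known limitations

* The directed Louvain is a greedy heuristic; it is tested to reach at
  least 95% of the exhaustive-partition optimum on small graphs, with no
  global guarantee beyond that.
* The lexicon approach scores words in isolation; sarcasm, negation and
  emoji are out of scope by design.
* The bootstrap is recursive residual resampling; wild-bootstrap and HAC
  variants are not implemented.
* Structural identification beyond the Cholesky ordering, cointegration,
  and Granger F-tests are out of scope.
* Language handling is single-vocabulary; multilingual token generation
  and language identification are not modelled.
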
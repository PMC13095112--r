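---
title: "Measuring partisan polarization in embedding space: methods and design notes"
author: "poliscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring partisan polarization in embedding space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(poliscope)
```

## The model

poliscope treats polarization as a geometric property of a labeled point
cloud. Each user is a point in an embedding space (their mean-pooled
tweet embeddings); each point carries a party or party-family label. If
partisan discourse has diverged, same-party users sit close together
relative to the population; if party labels are uninformative about
language, within-party distances look like a random draw from all
pairwise distances.

The index normalizes the within-party distance sum $S_w$ by its
attainable extremes. With $m$ the number of unordered within-party
pairs, and $S_{min}$, $S_{max}$ the sums of the $m$ smallest and largest
pairwise distances over the whole population,

$$\mathrm{poli} = \frac{S_{max} - S_w}{S_{max} - S_{min}} \in [0, 1],$$

which is one minus the C-index of the party partition. Two properties
make it suitable for comparing polarization across regions, weeks and
topics: it is invariant to rigid motions and positive rescaling of the
embedding space (all three sums scale together), and it is normalized by
the population's own distance distribution, so cells with different user
counts and embedding scales remain comparable.

Assumptions worth keeping in mind: distances are Euclidean (the distance
is configurable in principle, but Euclidean is the tested contract, and
mean pooling lives most naturally in a Euclidean geometry); each user
has exactly one label; and the index is a *relative* measure — it says
how clustered the parties are given this population, not how far apart
they are in absolute semantic terms.

Two degeneracies are handled explicitly rather than silently:

* **Degenerate partition** ($m = 0$, every party a singleton): no
  within-party pair exists, the index is meaningless, and the call
  errors.
* **Degenerate geometry** ($S_{max} = S_{min}$, e.g. all users
  coincident): the normalizer vanishes and no information about
  separation exists. The result is flagged undefined (`NA`) and excluded
  from downstream averages, never coerced to 0 or 1.

## Exact computation

The exact path materializes all $n(n-1)/2$ pairwise distances
(`stats::dist`), computes $S_w$ per party, and obtains $S_{min}$ and
$S_{max}$ by partial selection (`sort(partial = ...)`) rather than a
full sort: only the sums of the sorted prefix and suffix are needed, and
selection guarantees every element before position $m$ is no larger than
the $m$-th order statistic. Ties among equal distances therefore need no
tie-break — any arrangement of tied values leaves prefix and suffix sums
unchanged. Values are clamped to $[0, 1]$ against floating-point
excursions of order machine epsilon at the extremes.

Pair counts are accumulated in double precision ($|p|(|p|-1)/2$
overflows 32-bit integers around 66,000 users per party). A guard
(default 50,000 users) refuses exact computation where the distance
vector would be impractically large and points to the approximation.

## The subsampling approximation

For large populations the index is estimated from repeated stratified
subsamples. One round draws `repeats` subsamples at the current
`fraction`, scores each exactly, and computes the coefficient of
variation (sd/mean) of the repeated estimates; while the CV exceeds
`epsilon`, the fraction grows by `stepSize` and the round repeats. The
returned estimate is the mean over the final round's repeats (the
post-loop value of the procedure), not a pool over all rounds — earlier
rounds used smaller samples and would add bias, not information.

Parameter defaults (all dimensionless): `fraction = 0.01`,
`stepSize = 0.01`, `repeats = 10`, `epsilon = 0.05`. `epsilon` is a
ratio (0.05 = 5%); thresholds quoted in percent in parts of the
clustering literature should be divided by 100 before use here.

Design choices that the procedure's bare statement leaves open:

* **Stratified sampling.** Subsamples are drawn without replacement
  *per party*, with $\max(2, \mathrm{round}(f \cdot |p|))$ users per
  party. Uniform sampling can return subsamples in which no party has
  two members ($m = 0$, index uncomputable) and distorts party
  proportions at small fractions; stratification removes both failure
  modes while preserving the estimand.
* **Near-zero means.** When a round's mean index is below $10^{-9}$ the
  CV denominator substitutes $10^{-9}$: an all-zero round (a genuinely
  unpolarized sample) then has CV 0 and stops, instead of 0/0.
* **Reproducibility.** Each call uses one private RNG stream seeded from
  its configuration; repeats consume the stream sequentially, so the
  full per-round trace is reproducible bit-for-bit and the caller's RNG
  state is untouched.
* **Non-convergence.** If the fraction cap (default 1.0) is reached with
  the CV still above threshold, the best estimate is returned flagged
  `converged = FALSE` rather than raising.

### Accuracy regime and the generator's default separation

The approximation's error at a given `epsilon` is governed by how
concentrated the subsample index is. On two-family isotropic Gaussian
populations of 10,000 users (5,000 per family, $d = 8$, spread
$\sigma = 1$) we measure, averaged over 10 seeded runs:

| separation $\delta/\sigma$ | exact poli | subsample CV at 1% | mean abs. error |
|---|---|---|---|
| 4 | ≈ 0.87 | ≈ 0.02  | ≈ 0.005   |
| 6 | ≈ 0.97 | ≈ 0.006 | ≈ 0.0016  |
| 8 | ≈ 0.997 | ≈ 0.001 | ≈ 0.0003 |

(The table is descriptive of what the test suite and acceptance script
compute; the suite asserts the $\delta/\sigma = 8$ row's error bound.)
Real partisan social-media discourse, where the approximation was
characterized, occupies the concentrated regime: subsample estimates of
the index vary far less than the 5% stopping threshold already at the 1%
fraction. The generator's default `separation = 8` (with `sigma = 1`,
`d = 8` in tests) was therefore fixed, once, as the package's
"paper-scale" condition: strongly but incompletely separated clusters
(the index stays visibly below 1; total separation would be a separation
two orders of magnitude above the spread). At weaker separations the
estimator remains unbiased but its per-subsample variance — and hence
the stopped error — is larger, as the table shows; users measuring
weakly separated populations should tighten `epsilon` accordingly.

## Labeling, topics, geolocation

**Profile keywords.** A user is politically explicit if their profile
contains at least one party keyword. Matching is on word boundaries
after Unicode NFKC normalization and lowercasing, with multi-word
phrases as contiguous token runs — `gop` must not fire inside `gopher`.
Profiles hitting two or more parties are `ambiguous` and excluded from
seed sets: the rule stage exists to produce high-precision seeds, and no
principled tie-break exists. Keywords match literally, including negated
contexts ("never trump" fires); this is a known bias of any keyword
stage and is documented rather than patched with a fragile negation
heuristic. Built-in lexicons cover the two major US parties and the five
main Canadian federal parties, with the Canadian family map grouping
Liberal/NDP/Green against Conservative/People's Party; Bloc Québécois
and minor parties are outside the map and drop out at the merge.

**Label propagation.** Seed labels train a classifier on mean-pooled
user embeddings (contract: `fit`/`predict`); the reference classifier is
a seeded multinomial-logistic model with a light ridge penalty
(`decay = 0.01`). The penalty matters: on small linearly separable seed
sets an unpenalized logistic fit diverges and its boundary can hug one
cluster; the penalized fit keeps the boundary between clusters. Seed
labels always override predictions, and every family must contribute at
least 10 seeds.

**Topics.** Topic membership is rule-based and multi-label: every topic
with at least one matching hashtag or word-boundary text keyword. The
candidate-hashtag harvest keeps tags occurring at least `minCount`
(default 100) times, ordered by descending count with lexicographic
tie-break so exports are reproducible. Conspiracy tagging is
stance-agnostic — promotion and debunking are both *about* the topic.
A fine-tuned topic classifier can stand behind the same contract; the
keyword stage defines membership for everything tested here.

**Geolocation.** Two pluggable backends (the contract is simply
string → lat/lon or not-found) are reconciled by a consensus rule:
accept iff both found coordinates and they differ by at most one degree
*per axis* (closed bound — exactly one degree still passes). The
accepted coordinate is the midpoint, which is symmetric in the backends;
keeping either backend's coordinate would privilege one service
arbitrarily. Region assignment is closed-box containment with
lexicographic tie-break among overlapping boxes; the bundled
North-American table holds coarse bounding boxes for the 51 US regions
and 13 Canadian provinces/territories and is default plumbing, not a
precise geography.

## Conditioning, ranking, aggregation

Weekly series use Sunday-start weeks fully contained in the window;
October 11 2020 (a Sunday) anchors the reference 12-week grid, and the
88-day collection window October 9 2020 – January 4 2021 defines the
daily grid. Weekly cells pool each user's tweets over the whole week
into one embedding (rather than averaging daily indices): the week is
the unit of measurement, and pooling uses all of a user's within-week
language. Cells up to 2,000 users are scored exactly; larger cells use
the approximation (the threshold is configurable; the approximation's
error is largest for small populations, so the exact path covers them).
Cells lacking two represented families, or with fewer than two users in
a present family, are flagged unsupported — never zero-filled, since a
missing measurement is not "no polarization".

Region rankings average each region's defined weekly values; rank 1 is
the highest mean, ties break by region code. The "overall" ranking is
the unweighted mean of the per-topic means (lockdown, mask, vaccine by
default; conspiracy enters the analyses through tweet *shares*, not the
index). Topic aggregation over a country-level series is either the
unweighted mean over defined topics or a volume-weighted mean with
weights proportional to each topic's tweet volume in the period.

Event-triggered averaging aligns fixed half-width windows of a daily
series at event dates and reports per-offset mean and standard deviation
across events (sd 0 for a single event); events whose window leaves the
series span are dropped with a message. Correlation reports are
Pearson's r with a Fisher-z 95% interval (SE $1/\sqrt{n-3}$) and a
two-sided t-based p-value, delegated to `stats::cor.test`, which
implements exactly this construction. With small region counts the
interval is wide; the package reports it rather than hiding it.

## The synthetic-data generator

`generatePopulation()` draws one isotropic Gaussian cluster per family
(optionally scaled-t(3) for heavier tails), centroids `separation`
apart. `generateCorpus()` builds the full fixture world around it:
users with planted family and region, profiles carrying a family keyword
with probability `keywordRate`, location strings resolvable by a
two-backend fixture gazetteer that always agrees within the consensus
tolerance, tweets with timestamps uniform over the window and hashtags
drawn per `topicRates`, and tweet embeddings equal to the user vector
plus Gaussian noise. Everything is reproducible byte-for-byte from the
seed.

What the generator deliberately does **not** emulate: real tweet text
(placeholder text plus hashtags), bursty or event-driven posting (tweet
times are uniform), topic-dependent language (a user's tweets share one
base vector across topics), bots, geocoding errors, or label noise in
profiles. Passing tests on synthetic corpora therefore demonstrate that
the *pipeline computes the intended quantities* under known ground
truth — not that any particular real-world corpus is polarized. The
headline empirical correlations reported for real platform data cannot
be reproduced without that data and are out of scope here.

## Problem sizes used by the test suite

The suite exercises: oracle equivalence against an independent
brute-force double-loop implementation on 200 random populations of up
to 60 users (tolerance $10^{-12}$); invariance under relabeling, rigid
motions and scaling at $10^{-9}$; approximation accuracy at 10,000 users
($d = 8$, 10 seeds, mean absolute error $\le 0.001$, and no worse than
at 500 users); separation monotonicity over $\delta/\sigma \in \{0, 1,
2, 4\}$ at 200 users per family and 20 seeds; and a 10-seed end-to-end
pipeline on 4-region corpora with one high-separation region, checking
that profile-keyword labeling recovers all planted families and the
planted region ranks first. These sizes make the full suite run in a few
minutes while keeping every statistical check comfortably away from its
decision boundary.

## An end-to-end example

```{r pipeline}
cfg <- synthConfig(
  nUsersPerFamily = 40, d = 8, tweetsPerUserMean = 10,
  regions = data.frame(region = c("R1", "R2", "R3"),
                       separation = c(4, 1, 1)),
  keywordRate = 1, seed = 11)
corpus <- generateCorpus(cfg)

lab <- classifyProfile(corpus$users$profile_text, usPartyLexicon())
fams <- mergePartyFamilies(setNames(lab, corpus$users$user_id),
                           usPartyLexicon())

a <- gazetteerGeocoder(corpus$gazetteer, "osm")(corpus$users$location_text)
b <- gazetteerGeocoder(corpus$gazetteer, "arcgis")(corpus$users$location_text)
cons <- geocodeConsensus(a, b)
regs <- setNames(assignRegion(cons$lat, cons$lon, corpus$regions),
                 corpus$users$user_id)

tweets <- assignTopics(corpus$tweets, defaultTopicLexicon())
ser <- computeSeries(tweets, corpus$embeddings, fams, regs,
                     window = cfg$window, granularity = "weekly",
                     topics = c("lockdown", "mask", "vaccine"))
rankRegions(ser, topic = "overall")   # R1 ranks first
```

## Known limitations

* The index compares within-party cohesion to the population's own
  distance distribution; absolute index values are not comparable across
  embedding models.
* Keyword labeling inherits every bias of self-description and literal
  matching; the propagation stage amplifies whatever bias the seeds
  carry.
* The bundled region table is a coarse bounding-box approximation;
  overlapping boxes are resolved deterministically, not geographically.
* Weekly/daily conditioning assumes enough active labeled users per
  cell; sparse cells are flagged rather than estimated, so downstream
  averages silently condition on support.
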
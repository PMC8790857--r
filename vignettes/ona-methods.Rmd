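---
title: "Methods: confirmation, measures and synthetic surveys in onasurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confirmation, measures and synthetic surveys in onasurvey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onasurvey)
```

## The data model

A roster-based organizational survey asks each responding organization
about its relationship with every other organization on the roster, on
several relation layers. `onasurvey` fixes six layers: `overall` (any
purpose, binary), `intensity` (communication = 1 < coordination = 2 <
collaboration = 3), and four nutrition working relationships (`policy`,
`capacity`, `knowledge`, `implementation`), each rated on a frequency
Likert scale (not at all = 0 < rarely = 1 < sometimes = 2 < often = 3 <
very often = 4). Integer codes are fixed; labels are matched
case-insensitively against these exact strings and nothing else — a
mis-spelled response is a counted, reported error, never a silent guess.

The canonical input is long format: one row per (reporting organization,
alter, layer, response). Per-respondent questionnaire exports flatten to
this shape trivially, and it extends to new layers without schema changes.

Three distinctions matter and are kept throughout:

* **Reported absence vs missingness.** A respondent who did not mention a
  dyad reported its absence (value 0). A *non-respondent* reported
  nothing: its entire row is missing (`NA`), not zero.
* **Directed vs confirmed.** Matrices are directed until the confirmation
  rule is applied; all measures consume confirmed, symmetric networks.
* **Accepted vs dropped.** Every invalid input row, unconfirmable dyad and
  excluded non-respondent is counted and surfaces in the pipeline
  manifest. Confirmation discards data; the run record says how much.

## The confirmation rule

Dyadic reports are perceptions, and the two directions routinely disagree.
A relationship is *confirmed* when both organizations acknowledge it. For
ordinal layers the confirmed value is the minimum of the two directed
reports:

$$C_{ij} = \min(V_{ij},\; V_{ji})$$

so one report of "often" against one of "sometimes" confirms at
"sometimes", and a zero on either side leaves the dyad unconfirmed. The
binary rule is the special case of thresholding the minimum at existence,
and the implementation keeps that identity exact
(`confirm_binary(N) == binarize(confirm_ordinal(N), 1)` on ordinal
layers). The rule is idempotent, dominated by both directed reports,
monotone in each report, and commutes with node relabelling; all four
properties are tested on random instances.

Dyads with a non-respondent on either side are unconfirmable. By default
non-respondents are excluded from confirmed networks (`node_policy =
"respondents"`): a one-sided dyad can never satisfy the rule, so keeping
such nodes would only add structural zeros that depress density and
centrality denominators. `node_policy = "all"` retains them as structural
isolates, which is useful for plotting the full roster. The number of
unconfirmable dyads is always attached to the result.

## Measures and conventions

All measures operate on confirmed, binarized, undirected networks and are
reported as percentages. For $n$ nodes, degrees $d_i$ and geodesic counts
$\sigma_{st}$ ($\sigma_{st}(i)$ of them passing through $i$):

* density $= 100 \cdot \sum_{i<j} a_{ij} / \binom{n}{2}$;
* normalized degree centrality $c_i = 100 \cdot d_i/(n-1)$;
* normalized betweenness centrality
  $b_i = 100 \cdot \sum_{s<t,\,s,t \ne i} \frac{\sigma_{st}(i)}{\sigma_{st}} \Big/ \binom{n-1}{2}$,
  counting **all** geodesics per pair; pairs in different components
  contribute nothing (no harmonic or other disconnected-graph variant —
  surveyed networks contain isolates and this matches the plain geodesic
  definition);
* Freeman centralization
  $= 100 \cdot \sum_i (c_{\max} - c_i) / \text{max possible sum}$, with
  denominator $n-2$ for degree fractions and $n-1$ for betweenness
  fractions, so the star graph attains exactly 100% on both.

These are the standard Freeman conventions. Two identities pin the
implementation down and are asserted to machine precision: mean normalized
degree equals density on every binary symmetric network, and betweenness
equals an exhaustive BFS geodesic-enumeration oracle (tested on 200 random
graphs with $n \le 12$; betweenness itself is computed via igraph, the
oracle is independent of it). Internal computation is at full precision;
the report tables round to one decimal in percent, the customary precision
for such tables.

Degenerate inputs are refused rather than coerced: density needs
$n \ge 2$, centralization and betweenness $n \ge 3$, valued matrices must
be binarized explicitly, and a binarization threshold of 0 (which would
declare every dyad tied) is an error.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 1 | ordinal level a confirmed value must reach to count as a tie (1 = "rarely"/"communication": every confirmed tie) |
| `node_policy` | `"respondents"` | analysed node set (see above) |
| `seed` | 42 | plot-layout seed; measures are deterministic regardless |

The analysed $n$ is always taken from the data (the respondent set or the
full roster, by policy), never from a constant: with non-response the
right normalization base is a property of the run, not of the method.

## Multiplexity

The four confirmed, binarized nutrition layers — in the fixed order
policy, capacity, knowledge, implementation — are stacked and summed
elementwise, giving each dyad a score 0–4: the number of working
relationships it shares. Score-0 dyads are absent from the multiplex edge
list. Multiplexity counts layers, not intensities; a frequency-weighted
variant is deliberately out of scope.

## The synthetic generator

Raw sociometric matrices are usually confidential, so the package
validates itself against surveys it draws from a known ground truth.
`synthetic_spec()` describes, per layer, an undirected blockmodel: a pair
is tied with probability `p_in` (same organization type), `p_out`
(different types), or `p_broker` when the pair is cross-type and touches a
designated broker. Tied dyads draw an ordinal level from the layer's
conditional distribution. Directed reports are then emitted per direction:
with probability `discordance` a report deviates from the latent value —
half the mass omits it, half shifts it one level *down*, never up. The
one-sidedness is a modelling choice: the minimum confirmation rule guards
against over-claiming, so under-reporting is the conservative noise to
validate against; both halves are configurable. Non-respondents emit
nothing.

The defaults are the study conditions the package is built around: 50
organizations in the field's type mix (9 UN, 4 multilateral, 5 bilateral,
10 NGO, 5 academic/research, 1 intergovernmental, 5 foundation, 11
network), non-response 0.14 (so ~43 respondents), an overall layer around
20% latent density, nutrition layers between roughly 4% and 10% with
knowledge densest, frequency mass concentrated on "rarely" and "sometimes"
(0.45/0.35/0.15/0.05), intensity mass on communication (0.6/0.3/0.1), two
cross-type brokers, and discordance 0.15. Tie probabilities and type mix
were set once from those targets; the discordance value is this package's
assumption — organizational surveys publish no reporting-noise rates.

Randomness is reproducible by construction: one master seed, with
deterministic per-stage and per-layer substreams, so identical specs give
byte-identical survey files and partial re-runs re-draw identical layers.
The generator saves and restores the caller's RNG state.

What the generator does *not* emulate: cross-layer correlation (layers are
drawn independently, which makes high multiplexity scores rarer than in
real data where the same pairs cooperate on several fronts), degree
correction within blocks (real networks have heavier-tailed degrees),
intensity nested inside the overall relationship (a real questionnaire
only asks intensity where an overall tie exists), and any fit to a
specific empirical network. Passing recovery tests therefore shows the
pipeline recovers planted structure of this kind — not that any particular
empirical dataset would be recovered.

## Validation strategy and problem sizes

The test suite works at sizes where exhaustive oracles are feasible and
fast: closed-form graphs (star, cycle, complete, path), 200 random graphs
with $n \le 12$ against the brute-force betweenness oracle, exhaustive
star-maximality over all $2^{10}$ graphs on 5 nodes, 100-seed recovery
experiments on 42-node surveys (one planted broker at `p_broker = 0.5`
against `p_in = 0.25`, `p_out = 0.02`, discordance 0.1 must top the
betweenness ranking in at least 95 runs; within-type must exceed
between-type confirmed density in at least 99 runs of a homophilous
regime), and Monte-Carlo checks of the generator's tie rates against
binomial standard errors. End-to-end, a noise-free survey must reproduce
its latent ground truth *exactly* through parsing, building, confirmation,
binarization and multiplexity.

## Known limitations

* DL input/output covers the full-matrix, embedded-labels dialect only —
  the most interoperable variant; node-list and edge-list DL dialects are
  not read.
* Only the minimum confirmation rule is provided; maximum- or
  mean-symmetrizing variants are out of scope, as is imputation of
  missing dyads.
* Measures are binary-tie measures; valued centralities are not computed —
  the threshold is the surfaced knob instead.
* No inferential statistics on ties (ERGM/QAP) and no homophily statistic:
  clustering by type is something the plots show and the generator plants,
  not something the package tests on empirical data.
* Plot styling (three country-count shape bins 1–2/3–5/6–8, type colours,
  betweenness-scaled node sizes with a visibility floor) is a documented
  default, configurable via `plot_style()`, not an attempt to replicate
  any particular drawing tool's aesthetics.
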
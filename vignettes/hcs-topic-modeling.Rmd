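---
title: "From dose-response curves to diagnostic topics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dose-response curves to diagnostic topics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcstopics)
```

This vignette is the package's own account of its methods: the model, the
preprocessing conventions, the sampler, the diagnostic-topic statistic, what
the synthetic generator does and does not emulate, and the design choices
made where more than one reasonable convention existed.

## The model

Each *drug-hour* — one drug observed at one HCS measurement time — is a
document; the 10 assay endpoints are the vocabulary; the "count" of
endpoint $w$ in document $d$ is the discretized magnitude of that
endpoint's dose response. LDA then assumes each document is a mixture over
$K$ topics, $\theta_d \sim \mathrm{Dir}(\alpha)$, each token's topic
$z \sim \mathrm{Mult}(\theta_d)$ and each token's word
$w \sim \mathrm{Mult}(\phi_z)$ with $\phi_k \sim \mathrm{Dir}(\beta)$. Two
conditional probability tables summarize the fit: $p(\text{topic} \mid
\text{document})$, used by the class diagnostics, and $p(\text{word} \mid
\text{topic})$, used to rank and group endpoints. $K = 3$ throughout,
matching the three histopathology classes the analysis interrogates; model
selection over $K$ is deliberately out of scope.

The implicit assumption — that a multinomial over discretized magnitudes
is an adequate surrogate for continuous assay readouts — is the standard
compromise that makes the likelihood tractable; the discretization
resolution (100 bins) keeps the information loss small relative to assay
noise.

## Preprocessing conventions

Several steps admit more than one convention; the package fixes one
default each and exposes the alternative where a practitioner might
reasonably want it.

**Normalization.** Treatment curves are divided pointwise by the DMSO
control curve of the same endpoint and time point (fold of control, the
HCS convention). A `difference` mode subtracts instead. A zero control
value is an error naming the offending dose, not a silent `Inf`.

**AUC.** The doses form a 2-fold dilution series, so integration is over
$\log_2(\text{dose})$, where the grid is uniform; the trapezoidal rule is
used. Integrating $(\text{value} - 1)$ rather than the value itself makes
a no-effect curve score exactly 0, keeps sub-control responses legal
(negative AUC), and makes the result invariant to the dose unit. With 10
doses spanning 9 two-fold steps, a constant 2-fold activation scores
exactly 9.

**Discretization.** Each AUC column is divided into `n_bins = 100`
equal-width bins over its own $[\min, \max]$ range and entries are
replaced by their **1-based** bin index; the column maximum maps to 100
and a constant (zero-range) column maps entirely to bin 1. 1-based
indexing is a deliberate choice: a 0 count would remove a word from a
document and silently change the topic model's support, whereas bin 1
contributes minimal but non-zero weight. Equal-frequency binning
(empirical-CDF ranks) is available behind `scheme = "equal_frequency"` for
sensitivity analysis; it is more robust to outlier drugs but discards
magnitude information, and the default follows the range-division reading
of "divided into 100 bins".

**Orientation.** Columns of the AUC table are ordered time-major, then by
the fixed endpoint catalog; documents are ordered drug-major, then time
ascending. These orders are part of the output contract (byte-identical
reruns), not incidental.

## The sampler

Inference is collapsed Gibbs sampling over token-level assignments, with
$\theta$ and $\phi$ integrated out analytically. A variational fit would
also work; Gibbs was chosen because its small-instance behaviour can be
verified *exactly* against enumeration of all $K^N$ assignments, which
anchors the whole test suite (the CPT semantics agree in expectation).

Defaults: $\alpha = 50/K$, $\beta = 0.1$ (the usual Gibbs-LDA convention
for small vocabularies), 2,000 sweeps, 500 burn-in, every 10th state
retained. The CPTs are posterior means over the retained samples, each
smoothed by its prior: $(n_{dk}+\alpha)/(n_d+K\alpha)$ and
$(n_{kw}+\beta)/(n_k+V\beta)$. Averaging over samples rather than reading
a single final state reduces the variance of the downstream diagnostic
scores. The per-sweep collapsed joint log likelihood
$\log p(\mathbf w, \mathbf z \mid \alpha, \beta)$ is recorded for
convergence monitoring; on the default corpus it climbs from roughly
$-6.4 \times 10^5$ at the random start to a plateau near
$-3.6 \times 10^5$ well before burn-in ends.

Determinism: seeds are mandatory (no clock seeding), the token stream is a
pure function of the corpus (documents in corpus order, terms in catalog
order within a document), and the sampler uses R's RNG, so `set.seed`
fixes the entire trajectory. Ties anywhere (argmax of scores, endpoint
assignment, term ranking) resolve to the lowest index and are flagged
where they matter.

Topic labels are exchangeable across runs; every recovery statement in the
tests first aligns topics with `match_topics()`, an exact optimal
assignment over the $K!$ permutations maximizing summed cosine similarity
between topic-word rows ($K \le 8$; the study uses $K = 3$).

## Diagnostic topics

For a class setting with classes $c = 1..C$ and a fixed HCS time point
$t$, $\mu_{ck}$ is the arithmetic mean of $p(\text{topic } k \mid
\text{document})$ over the class's drugs, using the single document each
drug has at $t$. The significance score column-normalizes over classes,

$$S_{ck} = \frac{\mu_{ck}}{\sum_{c'=1}^{C} \mu_{c'k}},$$

so $\sum_c S_{ck} = 1$ for every topic, $S$ is invariant to rescaling a
topic column of $\mu$, and relabeling topics permutes $S$'s columns
identically. The diagnostic topic of class $c$ is
$k^* = \arg\max_k S_{ck}$, ties flagged.

Two design points were genuinely open. First, whether $\mu_{ck}$ at time
$t$ should pool documents across time points: the per-time-point form is
used because the score matrices are reported *per HCS hour*, and pooling
would blur exactly the temporal contrast (late-necrosis activation ramping
over time) the analysis is after. Second, the three evaluation settings
(necrosis at 6 h vs not; at 24 h vs not; at either vs neither) are built
from a plain label table rather than hard-coded drug lists, so real
histopathology labels drop in through the same `labels.tsv` dialect the
generator writes.

## The synthetic generator

The generator exists because the real assay measurements and
histopathology records are proprietary. It emulates the *design* of the
study — 122 drugs, 10 endpoints (8 distinct, Cell Loss and Nuclear Size
replicated across the two plates), 4 time points, a 10-point 2-fold
dilution series topping at 200 μM, matched DMSO controls — and plants a
latent structure of the same shape as the finding the analysis should
recover:

* endpoint event groups: {Steatosis, DNA Fragmentation, Mitochondrial
  Potential, Lysosome Mass}, {DNA Damage, Apoptosis}, {Cell Loss ×2,
  Nuclear Size ×2};
* class schedule: early-necrosis drugs activate group 1 at full strength
  from the first hour; late-necrosis drugs activate group 2 with strength
  ramping 0.25 → 1.0 across the four time points; non-necrosis drugs
  activate group 3 at half strength throughout.

An "on" endpoint follows a monotone logistic dose response on the
$\log_2$ dose axis, scaled so the fold-change shift at the top dose equals
`effect_size × activation` exactly; an "off" endpoint is the control
baseline. Gaussian noise (`noise_sd`, default 0.05 on the fold-of-control
scale) is added to treatment and control alike. Class proportions default
to 0.30 / 0.26 / 0.44, the 15 : 13 : 22 ratio of the in vivo necrosis
groups that motivate the labels, apportioned by largest remainder so
counts are deterministic; the generator emits one value per dose level
(no well replicates), an assumption stated here once.

What the generator does **not** emulate — and therefore what passing
recovery tests do *not* establish about real data: plate and batch
effects, heteroscedastic or heavy-tailed assay noise, non-monotone
(hormetic) dose responses, endpoint crosstalk across groups, drugs with
mixed or time-shifting class behaviour, and overlapping class memberships
(a real drug can show necrosis at both 6 and 24 h; the planted classes are
disjoint). Recovery on this generator shows the pipeline is *correct and
well-posed* — the statistic finds structure that is representable by the
model — not that real HCS campaigns contain such clean structure.

## Numerical choices and degenerate inputs

* Curves need ≥ 2 doses, strictly increasing and positive; violations are
  errors, not warnings.
* A constant AUC column discretizes to all-1; an all-zero topic column in
  the score matrix (impossible with smoothed CPTs, possible with
  hand-built means) is a hard error.
* Probabilities are smoothed by $\alpha, \beta > 0$, so CPT entries are
  strictly positive and row sums are 1 to within $10^{-9}$.
* Per-stage seeds in the pipeline derive deterministically from the global
  seed and the stage name, kept inside 32-bit range, so a stage can be
  re-run in isolation with the same result.

## Problem sizes used in validation

The validation studies are sized so the whole suite runs comfortably on
one CPU: the sampler-versus-enumeration checks use corpora of ≤ 6 tokens
and $K \le 3$ with 50,000 retained samples (enumeration is $K^N \le 729$
assignments); parameter recovery uses 488 documents of 380 tokens drawn
exactly from the generative process; the end-to-end recovery study runs
the full 122-drug pipeline across 20 independent seeds with an 800-sweep
schedule (the planted structure converges within a few hundred sweeps; the
2,000-sweep default is kept for one-off analyses where runtime is
irrelevant).

## Known limitations

Bin indices are treated as word counts, so a document's total token count
varies with response magnitude — an intended feature (stronger responses
carry more weight) but one that couples document length to class, which
pure LDA does not model explicitly. The diagnostic score is a descriptive
statistic: no significance testing is attached to score differences.
Exact numeric reproduction of score tables from the original assay
campaign is impossible without the proprietary inputs, and the original
hyperparameters and convergence criteria were never reported; agreement is
therefore assessed structurally (group partition, per-class diagnostic
topics, their constancy over time), not entry-by-entry.
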
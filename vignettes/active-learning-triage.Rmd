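---
title: "Active-learning triage of drug-safety DDI abstracts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-learning triage of drug-safety DDI abstracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical drug-drug interaction (DDI) toxicity evidence is scattered across a
literature in which relevant abstracts are a vanishing fraction of the whole.
A screening classifier for this setting must operate at very high recall --
missing a relevant abstract is costly, so the working requirement is recall
0.99 -- and the quantity worth optimizing is the precision achieved at that
recall (P@R=0.99). Two practical obstacles shape everything in this package:

1. **Labels are expensive.** Manually reviewed positives and negatives are
   scarce, and both come from the same keyword query, so the labeled
   negatives do not represent the general document population.
2. **The population is almost all negative.** A uniform draw from the
   literature ("random negative sampling") is almost free to collect and is
   overwhelmingly negative, but it follows a different distribution than the
   reviewed negatives, and it hides a small number of true positives.

`altriage` implements a pool-based active-learning (AL) framework that
combines uncertainty sampling with random negative sampling, trains **two**
classifiers for the two negative populations, and -- the central proposal --
**updates the external validation set** along with the training sets, so that
the yardstick tracks the evolving sample population.

## The four workflow variants

| variant | negatives in training | models | validation updated |
|---|---|---|---|
| `traditional` | reviewed negatives | one | no |
| `traditional_random_neg` | random pool draw | one | no |
| `dual_model` | both, separately | two | no |
| `dual_model_val_update` | both, separately | two | yes |

`ml1` discriminates positives from *random* negatives; `ml2` discriminates
positives from *reviewed* negatives. Each round the engine:

1. fits the variant's model(s);
2. scores the unlabeled pool and extracts a seeded random subset (budget 400
   by default) of the documents whose positive probability lies in the
   closed band **[0.4, 0.6]** -- the uncertainty samples;
3. when random negatives are in play, additionally sends every random-pool
   document scored **strictly above 0.7** to the oracle ("high-confidence
   positive mining": these are candidate positives hiding among the presumed
   negatives, and all of them are reviewed);
4. has the oracle label the acquired documents, routes them into the
   training set(s) -- and, for `dual_model_val_update`, splits them
   0.4 / 0.3 / 0.3 among `ml1`-training, `ml2`-training and validation --
   removes them from the pool, and refits.

Band endpoints are inclusive (the natural reading of "between 0.4 and 0.6");
the mining cut-off is strict because it is stated as an inequality. Newly
labeled positives enter both training sets; oracle-confirmed negatives enter
`ml1`'s random-negative stratum and `ml2`'s negative stratum (once reviewed,
they are manually labeled negatives in every meaningful sense).

### Which model scores the pool

With two models fitted, the framework needs to decide whose probabilities
define "low confidence". Scoring with `ml1` alone is tempting (it is the
model trained against the pool's own distribution), but it has a structural
blind spot: the documents `ml2` misranks -- background documents rich in
topics `ml2` never saw in training -- are exactly the documents `ml1` is
*most* confident about, so they would never be acquired and `ml2` could
never be corrected. The default is therefore `acquisition_model = "both"`:
the band is the union of the two models' bands, with the budget applied to
the union. High-confidence mining, by contrast, always uses the
random-negative model alone: a background-naive `ml2` calling a random-pool
document "positive" is usually evidence about `ml2`, not the document.
Single-scorer behavior remains available via `acquisition_model = "ml1"` or
`"ml2"`.

The engine keeps training, validation and unlabeled pools pairwise disjoint
at every round (asserted internally), which means documents drawn into the
random-negative training stratum are not re-scored as pool members. The
oracle's query counter grows by exactly the acquisition-log length, making
manual-effort accounting an invariant rather than a convention.

## Preprocessing

Documents are titles plus abstracts, lowercased, with every non-alphanumeric
character treated as a separator (hyphenated forms split) and pure-digit
tokens dropped. Tokens are reduced with the classic Porter stemmer,
implemented in the package and verified against the algorithm's published
example vocabulary ("advanced" and "advancing" both become `advanc`). One
caveat worth knowing: the canonical algorithm is not strictly idempotent for
a handful of English forms (`agreed` → `agre` → `agr`); over this package's
synthetic vocabulary, idempotence holds and is property-tested.

Counts are assembled into a term-document matrix (terms ordered
lexicographically in the C locale, so matrices are bit-reproducible) and
features are selected by the per-term **standard deviation of counts across
documents**: terms with SD strictly above 0.03 are kept. Near-constant
terms carry no discriminative signal; for a term appearing `k` times as
singletons among `N` documents the SD is about `sqrt(k/N)`, so the filter
removes the ultra-rare tail. The SD divisor is the population convention
(divide by `N`); the sample convention is a switch (`divisor = "n-1"`)
because at corpus scale the difference is negligible but worth making
explicit. There is no stop-word list and no TF-IDF: raw integer counts are
the features, and the SD filter is the only pruning.

## Classifiers

Both families share one contract: `fit_classifier(spec, x, y)` →
`predict_proba(model, x)` in `[0, 1]`, bit-reproducible for a fixed seed.

* **`logistic`** -- ridge-penalized logistic regression (glmnet), default
  `lambda = 0.05`, `standardize = FALSE` (counts share a scale). Its outputs
  are probabilities already.
* **`max_margin`** -- a linear hinge-loss SVM. The solver is dual coordinate
  descent for the L2-regularized L1-loss dual (the LIBLINEAR algorithm),
  compiled via Rcpp, with the bias handled as an augmented constant feature
  and a deterministic xorshift permutation schedule. The cost parameter is
  `1 / regularization`. A linear-specific solver matters here: with a few
  thousand sparse count features and ~1,200 documents it fits in well under
  a second, where a kernel-matrix SMO solver takes seconds per fit and the
  multi-seed study needs hundreds of fits. Margins become probabilities via
  **Platt scaling** fitted on 3-fold cross-validated decision values
  (stratified, seeded folds; prior-corrected targets; BFGS on the sigmoid
  likelihood). Requesting a max-margin model without calibration is an
  error whenever probabilities are consumed -- and the AL loop always
  consumes probabilities.

A linear kernel is the appropriate choice for high-dimensional sparse count
features; no other kernel is offered. Regularization defaults are config
values, not claims about any reference system.

## Evaluation

Recall `R = TP/(TP+FN)`, precision `P = TP/(TP+FP)`, `F1 = 2PR/(P+R)`, all
from a confusion matrix with "positive" as the event class; zero
denominators report 0 with a `degenerate` flag. Display rounding is
half-up at two decimals (`round_half_up()`), the convention of printed
results tables.

**Precision at recall** sweeps every threshold realized by the observed
scores (retrieval rule: score ≥ threshold). Among thresholds whose recall
reaches the target, the *highest* one -- the most conservative feasible
operating point, retrieving the fewest documents -- is selected and its
precision reported. Retrieving everything always reaches recall 1, so a
feasible threshold exists whenever positives do. With a couple hundred
validation positives, exact recall 0.99 is unattainable, which is why the
feasibility condition is `recall ≥ target` rather than equality. One
non-obvious consequence, worth stating because it surprises people: this
quantity is **not** monotone in the recall target. Raising the target
lowers the operating threshold, and precision along that path can rise
(scores `neg .9, pos .85, pos .8`: target 0.5 gives precision 1/2, target
1.0 gives 2/3). The implementation is verified against exhaustive
enumeration of all thresholds on hundreds of random instances instead.

`evaluate_uncertainty_subset()` scores a model on the oracle-labeled
documents acquired in an earlier round -- the hard samples -- so a
second-round model can be compared with the first-round model that selected
them. `distribution_diagnostics()` projects any document set onto its top
two principal components (computed by orthogonal subspace iteration on the
centred sparse matrix, deterministic initialization, checked against
`prcomp` on dense fixtures) and reports per-group centroids and their
distances; it is purely diagnostic.

## The synthetic corpus generator

No public corpus exists for this task, so the generator is a first-class
module: it defines the study conditions under which every end-to-end claim
is tested. Documents are drawn from a six-topic mixture-of-multinomials:

| topic | emulates |
|---|---|
| `pos_core` | DDI-safety-specific vocabulary |
| `drug_shared` | drug/pharmacology language shared by both labeled classes |
| `neg_specific` | content specific to reviewed negatives |
| `bg_shared` | general clinical/scientific prose, partially covered by reviewed negatives |
| `bg_specific` | background content no reviewed document covers |
| `filler` | a uniform ultra-rare block whose count SD falls below the selection threshold |

Class mixtures encode the failure modes the dual-model workflows exist to
fix. Positives and reviewed negatives share the drug topic heavily (both
came from the same query); positives also use general background vocabulary
(`bg_shared`, some `bg_specific`) that reviewed negatives only partly cover
-- controlled by `overlap_labeledneg_background`, the fraction of background
topic mass the labeled-negative class also covers. The background pool
contains drug-related documents and a trace of `pos_core` (it is drawn from
the same literature, so near-positives exist). Consequences, each asserted
in tests:

* a positives-vs-reviewed-negatives classifier overrates part of the random
  pool, including documents above the 0.7 mining threshold;
* the uncertainty band concentrates in the class-overlap region;
* in the two-component PCA plane, positives sit farther from the background
  centroid than from the reviewed negatives, and farther from the background
  than the reviewed negatives are -- the reviewed-negative class lies
  between positives and the pool;
* raising `overlap_labeledneg_background` degrades `ml2`'s first-round
  precision at the recall target (reviewed negatives absorb the shared
  background topic, dragging background-heavy positives down the ranking).

Per-document topic mixtures are drawn as
`0.35 * class_mixture + 0.65 * Dirichlet(4 * class_mixture)`. The Dirichlet
part creates within-class spread -- without it there are no uncertain
documents and no hard positives, and the whole acquisition machinery is
vacuous. The 0.35 floor bounds every document away from total topical
anonymity: the weakest positives are *hard*, not hopeless, which is what
makes second-round correction possible at all (a positive with literally no
positive-topic mass is unfixable by any amount of training, and a generator
that produces such documents pins P@R at prevalence forever). Document
lengths are Poisson (mean 180 tokens); tokens are rendered as deterministic
pronounceable words, 30% of them carrying an inflectional suffix
(`s`/`ed`/`ing`) so that stemming performs real work; titles are capitalized
and abstracts end with a period so normalization is exercised too.

The random pool hides true positives at rate 0.002 -- at the default pool
size, a binomial handful, matching the order of magnitude a screening
effort would plausibly recover per round. The ground-truth oracle labels
any document on request (optionally with a configurable flip rate for
robustness experiments) and counts every query.

**What the generator does not emulate:** Zipfian vocabulary growth, word
order and discourse (documents are bags of counts), indexing vocabularies
or metadata, and real inclusion/exclusion criteria (the oracle is exact by
default). Passing end-to-end tests on this corpus demonstrates that the
workflow's *mechanisms* behave as designed under the stated population
structure -- not that any particular precision level would be attained on
real literature.

## Study conditions and problem sizes

The headline experiment (`al_variant_study()`) runs the validation-update
and traditional variants, both classifier families, across 20 replicate
corpora: 600 positives, 400 reviewed negatives, and a random pool of 2,000
documents over a 5,000-word vocabulary, with the standard initial sets (200+
/ 200- / 1,000R training, 200/200/200 validation) and two rounds. The pool
is scaled to 2,000 (from the 9,200 a full-scale corpus would use) to keep a
replicated, multi-variant, multi-family study at desk scale; the pipeline
invariants are additionally exercised once on a full-size corpus. Across
seeds the study reports, per variant/family/model, the mean first- and
second-round P@R=0.99, the fraction of seeds where round 2 met or beat
round 1, and the same comparison for F1 on the round-1 acquired samples.

The qualitative pattern this recovers: with validation updating, `ml2`'s
P@R=0.99 improves from round 1 to round 2 in the large majority of seeds,
while the traditional workflow -- biased uncertainty samples, fixed
validation -- degrades in the majority; and second-round models beat
first-round models on the first round's own hard samples nearly always.
Absolute values are corpus-specific and are not comparable to any real
screening system's numbers.

## Numerical choices and degenerate inputs

* Every stochastic step consumes an independent seed derived from the
  master seed (multiplicative hash), so single steps are reproducible in
  isolation; model-fit seeds derive from the training-set size, so a no-op
  round refits bit-identical models.
* Model fitting refuses single-class training sets and feature-space
  mismatches; `precision_at_recall` refuses truth vectors without
  positives; empty uncertainty bands warn and return empty acquisitions
  (the round completes as a no-op).
* Term SD uses a cancellation-guarded `E[x^2] - E[x]^2` on sparse counts.
* The TSV dialect escapes tabs, newlines and backslashes for bit-exact
  round trips; the MEDLINE reader joins continuation lines with single
  spaces, keeps abstract-less records (with a message), and rejects
  records without a PMID.

## Known limitations

* Two rounds are the default study design; the engine supports more, but
  multi-round dynamics (e.g. budget exhaustion as the band drains) are not
  studied.
* The combined retrieval rule (`combined_retrieve()`, AND over both models)
  is an extension for deployment convenience; the evaluation protocol
  assesses the models separately.
* Probabilities from Platt scaling are calibrated only as well as 3-fold
  decision values allow on a few hundred training documents; band
  membership near the endpoints is therefore noisier for `max_margin` than
  for `logistic`.
* The generator's class mixtures are a stylized two-negative-population
  world; effect sizes on real corpora will differ.
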
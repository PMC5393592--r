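---
title: "Methods: distributional models for species-name inventories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distributional models for species-name inventories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A species is typically named many ways: a scientific binomial (*Actitis
macularius*), older synonymous binomials (*Tringa macularia*), and vernacular
names ("spotted sandpiper"). Search over biodiversity literature misses most
relevant documents when only one surface form is queried. `termspace`
implements the distributional route to this problem: names that denote the
same (or a related) taxon tend to occur in similar lexical contexts, so a
vector representation of each name's contexts — with relatedness measured by
cosine similarity — can surface semantic variants directly from a corpus,
including variants absent from curated taxonomies. The end product is a
*terminological inventory*: for every sufficiently frequent name, its corpus
frequency and its top-20 most related names with scores.

## Models

Six model variants are provided, all over the same tagged corpus in which
each dictionary name occupies a single token position (multi-word names are
rewritten as `chipping_sparrows`-style joined tokens).

**Count-based association vectors.** For each term we count co-occurrences
with every lexical unit inside a symmetrical window of `w` tokens (default
`w = 3`) on either side, never crossing document boundaries. Each vector
entry is the log-likelihood ratio (Dunning's G²) of the term–unit 2×2
contingency table:

$$G^2 = 2 \sum_{ij} k_{ij}\,\ln\frac{k_{ij}}{E_{ij}},$$

with expected counts $E_{ij}$ under independence and $0\ln 0 \equiv 0$. The
"log-likelihood ratio" of the collocation literature admits several
readings; Dunning's G² is the standard one and is what we implement.
Negative associations (observed joint count below expectation) are clipped
to zero by default — association vectors for similarity ranking care about
attraction, and clipping keeps vectors sparse — but `clip = FALSE` retains
signed behaviour for anyone wanting the raw statistic. Only the `d` most
frequent context units are kept as dimensions (default 150,000, which at
desk scale means "all units"); frequency is measured after stop-word
normalization, and ties in the top-`d` cut are broken lexicographically so
the dimension set is deterministic.

**Prediction-based embeddings.** `train_cbow()` is a continuous bag-of-words
model with negative sampling (the model predicts a token from the average of
its context-window vectors); `train_glove()` is a GloVe-style weighted
least-squares factorization of log co-occurrence counts optimized with
AdaGrad, with word and context vectors summed at the end. Both are
implemented in C++, single-threaded, with an internal xorshift RNG seeded
from the configuration: identical seed and configuration give
bitwise-identical vectors, which is the property the whole pipeline's
reproducibility contract rests on. Default dimensionality is 300 and window
3. The remaining hyperparameters follow the original model papers (CBOW:
5 negative samples, initial learning rate 0.05 with linear decay; GloVe:
weighting exponent 0.75, AdaGrad rate 0.05, `x_max` 100). On corpora far
smaller than the web-scale corpora those defaults were tuned for,
co-occurrence counts rarely approach 100, so benchmark runs pass
`x_max = 25` to keep the weighting function from suppressing every pair;
this is a corpus-scale adjustment, not a change to the shipped defaults.

**Additive composition (BAM).** A multi-word term $z = w_1 \cdots w_K$ can
alternatively be represented from the single-word vectors of its components:

$$v_{\mathrm{BAM}}(z) = \sum_{i=1}^{K} \frac{v(w_i)}{\lVert v(w_i)\rVert_2}.$$

The sum of unit vectors is deliberately *not* re-normalized — the model is
the plain sum, and cosine ranking is scale-invariant, so re-normalization
would be observationally void. A zero-norm component is an error rather than
being silently skipped (skipping would silently change the term's
semantics); terms with out-of-vocabulary components are excluded from the
composed space with a logged count. With $K = 1$ composition reduces to unit
normalization, so a BAM run over an all-single-word dictionary is a no-op up
to scale.

## Tagging and normalization

Dictionary matching is a greedy left-to-right longest-match scan (entries
capped at 6 tokens); greedy matching is deterministic and linear-time, and
on name dictionaries overlapping alternatives beyond the longest-match rule
essentially do not arise. Scientific names are matched case-sensitively on
the genus initial (the binomial convention: the generic name always carries
an uppercase initial) and case-insensitively elsewhere; vernacular names are
fully case-insensitive. A matched span is replaced by the entry's canonical
joined surface, which also collapses case variants onto one countable term.
Underscores already present in source tokens are escaped before joining so
composed terms can be split back unambiguously.

Context normalization lowercases, removes a fixed English stop-word list
shipped with the package, and optionally applies a deliberately light
rule-based lemmatizer (regular plural stripping). Dictionary terms are
always exempt — they must survive normalization to be vectorized.
Part-of-speech filtering is not implemented: no deterministic tagger is
available as a dependency, and the stop-word list covers the function-word
stratum that POS filtering would mostly remove. Document boundaries are hard
window boundaries; no sentence splitting is attempted because OCR-derived
text has unreliable punctuation.

## Evaluation

Rankings are scored against a reference standard mapping each preferred name
to its semantic variants, with four metrics over cutoffs $N = 1..20$: top-N
accuracy (share of queries with at least one correct variant in the top N),
precision@N, recall@N, and mean average precision. Name comparison
normalizes to a common key (spaces to underscores, case-insensitive), so
gold variants written as plain names match tagged candidates.

One convention required a decision: whether recall and AP denominators count
gold variants that the model could never retrieve because they are absent
from its vocabulary. We restrict denominators to in-vocabulary variants
(a model should not be punished for names the corpus never exhibited often
enough to vectorize) but record the unrestricted counts in every report, so
both conventions stay computable. Queries whose entire gold set is
out-of-vocabulary are excluded and counted. Statistical model comparison
(ANOVA-style tests over MAP) is deliberately out of scope; per-query AP
vectors are exported as TSV so any statistics environment can run them.

## The synthetic benchmark

Real inputs at the scale this method targets (tens of gigabytes of OCR
text, licensed taxonomies) are not shippable, so the package carries a
generator that emulates the statistical regime the models rely on, and all
claims verified by the test suite are claims about that regime:

* a Zipfian background vocabulary (exponent 1.1);
* planted synonym groups whose members are surrounded, with probability
  $\rho$ (the *signature rate*), by words from a group-specific signature
  set — the generator's encoding of "synonyms share context
  distributions";
* multi-word names emitted as plain adjacent words (the tagger joins
  them), with group members optionally sharing a genus or epithet
  component;
* standalone occurrences of component words embedded in *other* groups'
  signature contexts, emulating the fact that a genus word occurs across
  many species mentions — this is what makes composed vectors of
  unrelated-component names genuinely noisy, as they are in real corpora.

The standard benchmark is 500 documents of 200 background tokens over a
2000-word vocabulary, 20 groups of 2 members, signature size 15, $\rho =
0.9$, seed 1 — roughly 100k tokens, small enough that every model trains in
seconds yet large enough that recovery is statistically meaningful. On it,
all three model families are expected to place a planted synonym in its
partner's top-10 at accuracy ≥ 0.8 (the suite checks this).

The *compositional-regime* benchmark (`composition_benchmark_config()`)
stresses the additive model: all names are two-word names; group signatures
are drawn from a small shared pool (25 words) so groups are confusable; the
signature rate drops to 0.2; and component words receive heavy standalone
occurrence (20× the planting rate) inside wrong-group contexts. With
`shared_component_prob = 1` every variant pair shares exactly one component
word, so the composed vectors of partners share an identical summand and
composition should *help*; with probability 0 the components are all
distinct, composition inherits only the corrupted component vectors, and it
should *hurt*. The suite checks both directions of that inequality for each
model family as 5-seed means. These conditions were designed once, by
construction of the mechanism, and are not per-model tuned — the same data
feeds all six variants.

What the generator does **not** emulate: OCR noise, multilingualism,
polysemous vernaculars shared across taxa, abbreviation ambiguity
(*A. insignis*), Zipfian skew in *name* frequencies, and authority fields.
Passing the suite therefore demonstrates correctness of the machinery and
of the models' comparative behaviour under the assumed regime, not
performance on any real corpus.

## Numerical and design choices

* All counts are accumulated exactly as integers and converted to doubles
  before G² evaluation (the products in the expected-count formula overflow
  32-bit integers long before corpora get large).
* Cosine values are clamped to $[-1, 1]$ against round-off; ranking ties
  are broken lexicographically everywhere so that every ranking, inventory
  and report is reproducible byte-for-byte.
* Self-matches are excluded from candidate pools along with any candidate
  whose surface normalizes to the query's (case/underscore variants).
* The inventory's candidate pool is restricted to dictionary terms: the
  task ranks species names against species names, not against arbitrary
  vocabulary. A `pool` argument opens it up for exploration.
* The generator runs under a locally-seeded RNG and restores the caller's
  RNG state, so library code never perturbs a user's session randomness.
* Vector files use the word2vec text format (`"V D"` header) at 10
  significant digits, round-tripping within 1e-6.

## Limitations

Embedding quality at desk-scale corpora is limited by data, not by the
implementation; absolute MAP values from full-corpus runs are not
reproducible here (they additionally depend on unreported training
hyperparameters). The light lemmatizer under-normalizes irregular forms.
Abbreviated names are not expanded or disambiguated. The matcher is greedy:
a pathological dictionary could in principle shadow a longer cross-boundary
match, though name dictionaries do not exhibit this in practice.
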
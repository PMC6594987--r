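---
title: "Methods: rule-based, CRF and neural named entity recognition for neuroscience curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based, CRF and neural named entity recognition for neuroscience curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromine)
```

## The curation problem

Data-driven brain modelling needs experimental parameters — membrane
potentials, conductances, firing rates — harvested from the literature
together with the context that makes them usable: which neuron type, which
brain region, which organism, which channel or current. `neuromine`
implements the text-mining side of that workflow as eight entity types:
`BrainRegion`, `NeuronType`, `ModelOrganism`, `IonChannel`, `IonCurrent`,
`IonConductance`, `ExperimentalValue` and `Unit`. Three annotators are
provided — deterministic rules and dictionaries, a linear-chain CRF, and a
BiLSTM-CRF neural tagger — plus uncertainty-based active learning to decide
which sentences are worth sending to a human annotator, and strict/relaxed
span evaluation to measure all of it.

## Tokenization and offset conventions

All offsets are 0-based with an exclusive end, so `end - begin` is the
surface length. Two coordinate systems coexist:

* **raw** — offsets into the original document text, used by brat standoff
  files;
* **detokenized** — offsets over the token stream joined by single spaces,
  the convention used in token-per-line feature tables.

The tokenizer is rule-based: whitespace splitting, detachment of
leading/trailing punctuation (`: ( ) , ;` and sentence-final `. ! ?`), and
splitting of hyphenated compounds *before* the hyphen, so `Whole-cell`
becomes `Whole`, `-cell`. Decimals (`12.5`) and digit-adjacent hyphens
(`10-20mv`) are never split, which keeps numeric expressions recoverable by
the value detector. Tokenization is idempotent under space-joining, a
property the test suite checks on generated sentences.

Sentence splitting is a `. ? !`-plus-uppercase rule with an abbreviation
guard list (`e.g.`, `et al.`, `Fig.`, single initials). It is a pragmatic
substitute: nothing downstream depends on a particular sentence inventory,
only on sentences being stable and offset-consistent.

## The rules engine

**Dictionaries.** Six entity types carry curated dictionaries (50–200
entries each, bundled as plain text). Matching is leftmost-longest over
token sequences. Entries of three characters or fewer (acronyms such as
`VPM`) match case-sensitively; longer entries match case-insensitively.
This keeps `vpm` in running prose from matching the acronym while still
letting `Ventral posteromedial nucleus` match at sentence starts. The
ion-conductance dictionary is generated from the ion-current dictionary by
the naming correspondence between the two: `current` becomes `conductance`
and acronym-initial `I` becomes `g` (`IH` → `gH`); a test asserts the
bundled file equals that rewrite.

**Noun-phrase regexes.** Neuron types, channels, currents and conductances
also get pattern rules scoped to noun phrases: when a phrase contains
`neuron(e)s`/`cell(s)`, `current(s)`, `channel(s)` or `conductance(s)`, the
*whole* noun phrase becomes a span of that type, so `T-type Ca2+ channels`
is annotated in full rather than just its head word. Noun phrases come from
a bundled chunker: a small POS lexicon with suffix fallbacks, then a
regex-over-POS pass (optional determiner, then adjectives/numbers/nouns).
Any backend honouring the B-/I-/O chunk-column contract can replace it.

**Values and units.** Numeric values are found with
`\d+(,\d{3})*(\.\d+)?`, which accepts `1100`, `23,400,500` and `12.5` but
rejects candidates embedded in malformed decimal or thousands context —
`1.1.1.1` and `1,23` yield nothing, implemented as a rejection of
candidates flanked by a digit-adjacent `.` or `,`. A directly preceding
minus sign (ASCII `-` or Unicode `−`, up to one intervening space) is
absorbed in post-processing unless the preceding token is itself a number,
which keeps `10-20` from turning its 20 negative while `−100 to − 40`
yields two negative values. Sample sizes (`n = 12`) are excluded by a
preceding-token guard. The unit gazetteer holds 24 base units and 19
prefixes with short forms; expansion produces every long combination
(`milligram`, `kilometre`; 24 × 20 forms), every short combination (`mg`,
`km`, `mm`) and mixed long-prefix/short-base forms (`microM`). Long forms
match case-insensitively with an optional plural; any form containing a
short component matches case-sensitively, so `mV` is not `MV`. The volt
entry carries a lowercase alternate short form because lowercase `mv`
occurs in practice. The base/prefix inventory is an SI-based
reconstruction, not a copied resource.

**Linking.** A value is linked to a unit when both fall in the same noun
phrase; the chunker deliberately keeps coordinated number lists (`15, 30
and 45 millimetres`) inside one phrase so a trailing unit reaches every
listed value. When the unit directly follows a value, the emitted
`ExperimentalValue` span is extended to include it (`12.5 microM`).

**Acronyms.** Parenthetical abbreviations (`suprachiasmatic nucleus
(SCN)`) are detected locally with in-order character-overlap validation
against the preceding words: the long form is the shortest span whose first
word starts with the short form's first letter and which contains all but
at most one of its letters in order. The one-letter slack is intentional —
initialisms like `POm` for `posterior nucleus` carry a letter with no
counterpart in the long form. If a long form is annotated anywhere in the
document, every standalone occurrence of its short form inherits the type.
Propagation is per-document.

## The linear-chain CRF

One model is trained per entity type over the three labels `B-T`, `I-T`,
`O`. Emissions are sparse indicator features on the word, lemma, POS,
chunk and dictionary columns in a ±2 token window (the window is a
configuration knob, and the dictionary column can be ablated without API
changes); transitions are a dense 3×3 matrix plus an initial-label term.
Training minimizes the L2-penalized negative log-likelihood — penalty
`||w||² / 2c` with `c = 1` by default — by L-BFGS with exact
forward–backward gradients. There is no stochastic element: identical data
and settings give identical weights, and the seed is recorded as model
metadata.

Because normalization is exact, the N-best decoder returns true
conditional probabilities: `P(y|x) = exp(score(y) − log Z(x))`, and
summing over all `3^n` label sequences gives 1 to floating-point accuracy
(a test enumerates all sequences on short sentences and compares at
1e−9). N-best decoding is a k-best Viterbi pass that keeps the top k
hypotheses per label per position; ties break toward the lexicographically
smaller label sequence (B < I < O), making rankings deterministic.

## Active learning by normalized sequence entropy

For an unlabelled sentence the decoder's top-N hypotheses (N = 3 by
default) give probabilities `p₁ ≥ … ≥ p_N`. These are renormalized by
their sum, their Shannon entropy is computed in base 2, and the result is
divided by `log₂ N`, giving a score in [0, 1]: 1 for a uniform top-N
(maximal model confusion), 0 when all mass sits on one sequence. Sentences
with fewer than N possible sequences keep the `log₂ N` denominator so
scores stay comparable across the pool. Selection returns the top-K
sentences by score (defaults N = 3, K = 500), with ties broken by pool
order for determinism. The test suite checks the benchmark property that
motivates the criterion: across five seeded pools dominated by
uninformative distractor sentences, a CRF retrained on K entropy-selected
sentences attains at least the mean F1 of one retrained on K random
sentences.

## The BiLSTM-CRF neural tagger

The network follows the standard character-aware architecture: per word, a
character BiLSTM produces the concatenation of its two final hidden
states; this character-based word representation is concatenated with a
word embedding; dropout is applied to the concatenation; a word-level
BiLSTM produces contextual representations; a linear layer yields
per-label emissions; and a CRF output layer defines the loss (sentence
negative log-likelihood) and the decoder (global Viterbi). The default
configuration is 20 epochs, batch size 10, 25-dimensional character
embeddings, 200-dimensional word embeddings, a 250-dimensional
character-based word representation — interpreted as 125 hidden units per
character-LSTM direction, since the per-direction size is a free choice —
dropout 0.5, and Adam with learning rate 0.013 and weight decay 1e-4. The
word-LSTM hidden size defaults to 100 per direction and is configurable.

Implementation notes:

* Forward and backward passes are hand-written in C++ (RcppArmadillo); a
  finite-difference gradient check in the test suite validates every
  parameter group to 1e−5 relative error.
* One Mersenne Twister seeded from the configuration drives parameter
  initialization, dropout masks and epoch shuffling, so training is
  reproducible bit-for-bit on one platform.
* Batches accumulate per-sentence losses and gradients before each Adam
  step; this is mathematically identical to padding with a masked CRF
  loss, and a test asserts batch loss equals the sum of per-sentence
  losses.
* Pretrained word2vec-binary embeddings are optional. In-vocabulary rows
  initialize the embedding table (verified against an independent
  read-back of the file); unknown words stay randomly initialized; naming
  a missing file is an error, never a silent fallback. Embeddings are
  matched case-sensitively first because biomedical casing (`mV`,
  `CaV3.1`) is meaningful. Embeddings remain trainable by default.
* Dropout is disabled at inference, and the Viterbi tie rule matches the
  CRF module's (lower label index wins), so inference is deterministic.

Test problems use reduced sizes (32-dimensional word embeddings,
24-dimensional character representations, 32 hidden units, 12 epochs,
roughly 100–150 template sentences), chosen so the whole suite trains
several models from scratch while remaining quick on a single CPU; the
architecture code paths are identical at full size.

## Evaluation

Spans are scored strictly (exact boundary equality) or relaxed (any
character overlap). Each gold span is creditable at most once, via greedy
left-to-right pairing, so several predictions overlapping one gold span
cost false positives rather than inflating recall; on non-nested span
sets this greedy pairing loses no matches relative to optimal matching,
and nested constructions are the known exception. With zero predictions,
precision is defined as 0, the conservative convention of NER shared
tasks. Inter-annotator agreement is strict-match F1 with one annotator as
reference; it is symmetric in F1 (precision and recall swap under
exchange) and never rewards agreement on unannotated text. The corpus
split shuffles sentences under a seed and cuts 70%/15%/15%, with rounding
remainders going to the training partition.

## The synthetic corpus generator

No external corpus is required: the generator emulates the *structure* of
curated neuroscience abstracts — template sentences with typed slots over
per-type lexicons, weighted primary-slot types, distractor sentences with
no entities, numeric ranges with Unicode minus signs, unit-final value
lists, parenthetical acronym introductions, and overlapping
region-inside-neuron spans. A fraction of each lexicon is held out and
sampled occasionally, so taggers see surface forms absent from most of the
corpus. All sampling flows from one RNG seeded once per run; identical
configurations give byte-identical corpora.

What it does *not* emulate: real PubMed prose statistics, boundary
ambiguity between annotators, rare or malformed entity variants, and the
lexical diversity of genuine full-text articles. Passing the recovery
criteria (span F1 ≥ 0.9 for both the CRF and the neural tagger on a
held-out 70/15/15 test split) therefore demonstrates that the
implementations learn and decode correctly under unambiguous lexical
cues — it does not predict performance on real corpora, where published
taggers of this family score substantially lower.

## Numerical choices and degenerate inputs

* All chain computations run in log space with a max-shifted log-sum-exp.
* Dangling `I-` labels during decoding are repaired to `B-` with a
  warning, making BIO decoding total.
* Annotations crossing token boundaries snap outward by default (or
  reject, by policy).
* Empty text tokenizes to an empty table; empty sentences tag to empty
  label vectors; all-`O` training data is a hard error for both taggers.
* Training the CRF uses `optim`'s L-BFGS-B with a convergence factor of
  1e7 and up to 150 iterations by default; the objective caches its
  gradient so function and gradient evaluations share one
  forward–backward pass.

## Known limitations

* The bundled POS tagger and chunker are intentionally small; on text far
  from the biomedical register their chunk boundaries (and therefore
  value–unit linking) will degrade.
* Bare short units (`m`, `g`, `T`) can false-positive on stray capitals;
  the deterministic annotator is expected to be the low-precision baseline
  of the three taggers.
* Relation extraction, ontology normalization, and linking a value to the
  physiological variable it measures are out of scope.
* brat discontinuous (`;`-offset) annotations are not supported.
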
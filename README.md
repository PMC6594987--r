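# neuromine

Named entity recognition and active learning for curating experimental
information from the neuroscience literature.

Building biophysically detailed brain models means harvesting measured
parameters — membrane potentials, conductances, firing rates — from
thousands of papers, together with the context that makes a number usable:
the neuron type it was measured in, the brain region, the organism, the
channel or current involved. `neuromine` is an R toolkit for that curation
workflow. It annotates eight entity types (`BrainRegion`, `NeuronType`,
`ModelOrganism`, `IonChannel`, `IonCurrent`, `IonConductance`,
`ExperimentalValue`, `Unit`) with three taggers of increasing power, and
decides which sentences deserve human annotation next.

## What is inside

* **Corpus I/O** — offset-exact rule-based tokenization, sentence
  splitting, BIO span encoding/decoding, brat standoff (`.txt`/`.ann`) and
  token-per-line TSV readers/writers with lossless round trips.
* **Rules and dictionaries** — leftmost-longest dictionary matching with
  acronym-aware case handling, noun-phrase-scoped entity regexes, a unit
  gazetteer (24 base units × 19 prefixes, long/short/mixed forms), numeric
  value detection (`\d+(,\d{3})*(\.\d+)?` with malformed-context
  rejection and negative-sign post-processing), value–unit linking within
  noun phrases, and document-level acronym propagation from parenthetical
  definitions.
* **Linear-chain CRF** (`crf_train`, `crf_predict`, `crf_nbest`) — one
  model per entity type over `B/I/O` labels, sparse window features,
  L-BFGS training with exact forward–backward gradients, and k-best
  Viterbi decoding whose hypothesis probabilities are exact conditional
  probabilities `P(y|x) = exp(score(y) − log Z(x))`.
* **Active learning** (`normalized_entropy`, `select_batch`) — sentences
  ranked by the normalized entropy of the top-N decoded sequences,

      H(x) = − Σᵢ (pᵢ/Σⱼpⱼ) · log₂(pᵢ/Σⱼpⱼ) / log₂ N  ∈ [0, 1],

  with defaults N = 3 and batch size K = 500.
* **BiLSTM-CRF neural tagger** (`nn_train`, `nn_tag`) — character BiLSTM
  word representations concatenated with word embeddings, dropout, a word
  BiLSTM, and a CRF output layer; hand-written C++ backprop with Adam,
  optional pretrained word2vec-binary embeddings, fully seeded.
* **Evaluation** (`prf`, `agreement_f1`, `split_corpus`) — strict and
  relaxed span matching, inter-annotator agreement as F1, and the seeded
  70/15/15 train/test/validate split.
* **Synthetic corpora** (`generate_corpus`, `generate_al_pool`) — a
  seeded template generator of neuroscience-like annotated documents
  (overlapping spans, numeric ranges, unit-final lists, acronyms,
  distractors) so every statistical stage is trainable and testable
  offline.
* **CLI** — `inst/cli/neuromine.R` exposes `gen-fixtures`,
  `annotate-rules`, `train-crf`, `tag`, `nbest`, `select-al`, `evaluate`
  and `run` as subcommands over the same functions.

## Worked example

Rule-based annotation of a sentence with a parenthesized concentration:

```r
library(neuromine)
s <- paste("The effect of bicuculline (12.5 microM) on the spontaneous",
           "firing rate of SCN neurons during the night was heterogeneous.")
annotate_rules(s)
#>         entity_type begin end     surface     source
#> 3 ExperimentalValue    27  38 12.5 microM      regex
#> 2              Unit    32  38      microM dictionary
#> 1        NeuronType    74  85 SCN neurons      regex
```

The value detector finds `12.5`, the gazetteer finds `microM`
(long prefix + short base form of molar), and because both sit in the same
noun phrase they are linked into one `ExperimentalValue` whose surface
includes the unit. `SCN neurons` comes from the noun-phrase regex for
neuron types.

Training a CRF on a generated corpus and inspecting its N-best
uncertainty:

```r
cfg    <- generator_config(seed = 21, n_documents = 18,
                           sentences_per_document = 8)
corpus <- generate_corpus(cfg)
sents  <- corpus_sentences(corpus, "BrainRegion")
sp     <- split_corpus(length(sents), seed = 1)
model  <- crf_train(sents[sp$train], "BrainRegion", seed = 1)
model
#> <nm_crf BrainRegion: 1988 features, window 2, penalized NLL 22.852>

feat <- build_features(tokenize("spikes arose in the caudal parafascicular nucleus"),
                       NULL, "BrainRegion")
hyps <- crf_nbest(model, feat, 3)
sapply(hyps, `[[`, "probability")
#> [1] 0.8770 0.0635 0.0168
normalized_entropy(sapply(hyps, `[[`, "probability"), 3)
#> [1] 0.3013408
```

A sentence the model is sure about scores near 0; a confusing one scores
near 1, and `select_batch()` ranks an unlabelled pool by exactly this
score to pick the next annotation batch.

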
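---
title: "Interoperable annotation formats and dictionary-based concept recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interoperable annotation formats and dictionary-based concept recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioconc)
```

## What the package does

`bioconc` covers two connected pieces of biomedical text-mining
infrastructure. The first is a format layer: readers, writers and a
bidirectional transcription between the BioNLP shared-task standoff format
(document text in a `.txt` file, annotations as plain-text `T`/`E`/`M`/`R`/
`*Equiv` lines in `.a1`/`.a2` companions) and BioC XML (a collection tree of
documents, passages and sentences carrying annotations with locations and
role-bearing relations, all decorated with key-value infons). The second is
a concept-recognition stack of the kind used for assisting Comparative
Toxicogenomics Database (CTD) curation: dictionary matching against
controlled vocabularies of chemicals, genes, diseases and action terms,
silver-standard corpus generation with false-positive filtering,
begin-inside-outside (BIO) labelling for external sequence labellers,
document-level multilabel action-term assignment, and concept-level
micro-averaged evaluation.

## The transcription scheme

Standoff annotations map onto BioC as follows. Entities keep their `T` ids
and become `<annotation>` elements with infons `typeUri`, `type=Entity` and
`category`, plus a single `<location offset length>` in document-level,
0-based, end-exclusive character coordinates (a span 19–49 has
`offset="19" length="30"`). Event triggers become annotations with the
deterministic id `TRIGGER_<begin>_<end>`; events sharing a trigger span
share the annotation. Events become `<relation>` elements keeping their `E`
ids, with `negation`/`speculation` infons that are `"true"` exactly when a
corresponding `M` modification exists, a first node with role
`EventTrigger`, and one node per argument with its role copied verbatim;
arguments that point at other events reference the target relation id.
Equivalence groups become `type=Equivalent` relations with empty-role
nodes. Coreference links that share a subject merge into a single
`type=Coreference` relation (id `R` + subject id) with one `Subject` node
and the `Object` nodes in source order, so a chain of k links yields k+1
nodes.

Every element produced by the transcription carries exactly one `type` and
one `typeUri` infon. A type URI is `uima:ts:` plus a dot-qualified type
name; the qualified names default to a `uk.ac.nactem.bionlpst.*` family and
are configurable through `type_uri_map()`, since no fixed vocabulary of
qualified names is part of the BioC format itself. We give trigger
annotations a `typeUri` as well, keeping the one-type-one-URI rule uniform
across all element kinds.

The inverse direction regenerates standoff ids where the scheme discards
them: triggers are re-issued fresh `T` ids (continuing after the highest
entity id) with the category recovered from the referencing event relation,
and each `Object` node of a merged coreference relation is expanded back
into its own `R` link. Round-tripping is therefore the identity *modulo*
trigger and coreference ids, which is what the round-trip tests assert via
a canonical structural form. A trigger referenced by events of conflicting
categories yields one `T` line per distinct span-category pair, with a
warning. Equivalence relation ids are `EE1`, `EE2`, ... in document order: a
deterministic counter, documented here because the id scheme for these
relations is otherwise arbitrary.

Character offsets count Unicode code points, not bytes. Byte offsets are
deliberately unsupported; a conformance caveat worth knowing when
exchanging non-ASCII BioC with other tools.

## The matching pipeline

All matching operates on a canonical token form produced by four steps:
case normalization, tokenization on non-alphanumeric boundaries (hyphens
and slashes separate, so chemical names fragment predictably), stop-word
removal, stemming, and alphabetical reordering. For example both
`"injured by stun gun"` and `"Stun Gun Injury"` canonicalize to:

```{r}
canonicalize("injured by stun gun")$tokens
canonicalize("Stun Gun Injury")$tokens
```

The stemmer is classic Porter (1980) — written out in this package —
followed by stripping a single trailing `"i"`, which reconciles pairs like
*injury*/*injured* (`injuri` vs `injur` under vanilla Porter) to a single
stem. Stemming is iterated to a fixpoint (at most 5 rounds): stripping one
suffix can expose another (*regulatory* → *regulator* → *regul*), and the
fixpoint makes canonicalization idempotent for any pluggable stemmer, a
property the test suite checks. The stop-word list is a small built-in
English function-word list, replaceable by a file.

Three operations build on the canonical form:

* **Exact matching** finds whole-token, case-insensitive occurrences of any
  vocabulary surface form (preferred names and synonyms), selecting
  leftmost-longest among overlapping candidates. Ambiguous names are
  matched like any other — the chemical *lead* will match the verb *lead* —
  because disambiguation is the filtering step's job, not the matcher's.
* **Approximate matching** scores each candidate phrase against each
  surface form by the number of common canonical tokens (multiset
  intersection; symmetric). A phrase matches when its best score is
  *strictly greater* than the threshold; the default threshold of 1 (at
  least two shared tokens) is a package choice, configurable because no
  single value is canonical. The emitted span is the minimal contiguous
  sub-span of the phrase covering the common tokens; per phrase only the
  highest-scoring entry survives, ties going to the longer preferred name
  and then the lexicographically smaller concept id.
* **Response normalization** maps a recognized span back to a vocabulary
  entry: a direct case-insensitive hit on any name or synonym wins
  unconditionally; otherwise the highest common-token score decides, and a
  zero best score returns nothing.

## Silver-standard corpus generation

CTD-style development corpora list each document's curated concepts as
unique preferred names, without text locations. To train a sequence
labeller one needs locations, so the pipeline plants them: exact matching
proposes candidate spans in all categories; for diseases — whose names are
frequently inflected in text (*leukopenic* for the curated *leukopenia*) —
approximate matching over candidate noun phrases adds spans that exact
matching cannot reach. Candidate phrases come from externally supplied
noun-phrase chunks when available, and otherwise from all 1–6-token
sliding windows within sentence bounds.

Every proposed span is kept only if its surface normalizes to a concept
present in the document's gold list for that category. This local filter
reproduces the effect of screening matches against per-document curated
concept lists: ambiguous false positives (the *lead* case) normalize to
concepts outside the gold list and are dropped. Survivors are reduced to
leftmost-longest non-overlapping spans per category — BIO labels cannot
express overlaps — and every occurrence of a surviving name is annotated,
not just the first. BIO emission writes one
`token<TAB>begin<TAB>end<TAB>label` line per token with blank lines between
sentences; `decode_bio()` inverts it, and encode/decode is bijective on
non-overlapping span sets. Sentence splitting defaults to a regex on
sentence-final punctuation followed by whitespace and an upper-case letter;
it is deliberately simple and pluggable, since production pipelines use
dedicated splitters.

## Action-term assignment

Action terms describe chemical–gene interaction types and rarely appear
verbatim, so assignment is document-level multilabel classification over
the label vocabulary (53 labels in the CTD set). Two feature families are
extracted per verb lemma of a biomedical verb lexicon: a boolean flag set
when any surface variant of the lemma occurs as a whole token, and a
co-occurrence weight accumulated over sentences where a variant occurs
together with at least one chemical and one gene mention. Each such
occurrence contributes `1/(1+d)`, `d` being the token distance from the
verb to the nearer of the closest chemical and the closest gene; distances
are counted in tokens and co-occurrence is confined to one sentence, since
proximity across sentence boundaries is not meaningful without parsing.
Accumulated weights are normalized by their maximum over all lemmas, which
bounds them in [0, 1] and makes them invariant under document duplication.
Both the weight function and the normalizer are configurable; the `1/(1+d)`
form and max-normalization are package choices among the reasonable
options.

Decisions are one-vs-all: each label has an independent linear scorer and
fires when its score strictly exceeds the threshold (default 0), so the
assigned set may be empty or arbitrarily large, and raising the threshold
can only shrink it. The default scorer is ridge-regularized least squares
on ±1 targets with an unpenalized intercept. We chose the closed form over
an online learner deliberately: it is deterministic and entirely
independent of example order, and on perfectly contradictory training data
(identical feature vectors labelled both ways in equal numbers) the fitted
score is exactly zero by symmetry, so no label fires — the behaviour one
wants from "scores at chance". Online perceptron-style learners only
approximate that, with a sign that depends on presentation order. The
`seed` argument remains in the interface for compatibility with learners
that do randomize. A label with no positive (or no negative) training
example gets a scorer that never fires, with a warning.

## The synthetic-corpus generators

Everything above is testable offline through seeded generators
(`fixture_spec()`, `gen_vocabulary()`, `gen_abstracts()`,
`gen_standoff()`). They are pure functions of the spec and seed — the
global RNG stream is saved and restored around each call — and they
emulate exactly the features the pipeline is sensitive to:

* vocabularies with 2–3-token names whose token sets are disjoint across
  entries, synonyms built as token permutations or one-token replacements
  (so every synonym shares canonical tokens with its preferred name);
* abstracts of pseudo-word filler sentences with planted mentions, where
  concept-name tokens and filler tokens come from disjoint syllable
  alphabets — a planted surface can therefore occur nowhere else, and the
  planted-span ledger is exact ground truth;
* morphological variants (a head-token inflection from {-s, -ed, -ic,
  -ing}, which exercises the stemmer reconciliation rule) planted for
  disease mentions at a configurable rate;
* distractors — mentions of vocabulary concepts deliberately absent from
  the document's gold list — that the silver filter must remove;
* standoff documents with entities, nested events, modifications,
  equivalence groups and subject-sharing coreference chains.

Default generator settings are modest (20 documents, 28 vocabulary
entries, synonym rate 0.5, variant rate 0.3, distractor rate 0.2, 2 events
per document on average); the test suite scales document counts per check
(up to 200 for the round-trip suites, 100 for the matcher-oracle and
evaluation checks, 40 + 40 for silver recovery and filtering, 80 training
and 40 held-out feature vectors for the action learner).

What passing these tests shows — and what it does not. The generators
plant unambiguous, token-aligned mentions in lexically clean text, so the
tests verify the machinery exactly: parsing, transcription, canonical
forms, span arithmetic, filtering logic, label bookkeeping and metric
computation. They do not emulate real abstracts: no shared tokens between
concept names, no abbreviations, no genuine syntactic structure, no
realistic ambiguity beyond the planted distractors. Performance figures on
these corpora (recovery at 100%, action micro-F at 1.0) are correctness
checks of the implementation, not estimates of recognition quality on real
literature, which depends on vocabulary coverage and trained sequence
models that are outside this package's scope.

## Evaluation semantics

`micro_prf()` scores per-document concept *sets* (duplicates collapse), in
the track's concept-level fashion: every gold and predicted name is mapped
case-insensitively through the vocabulary — preferred names first, then
synonyms — and true/false positives and false negatives are summed over
all documents *before* precision, recall and F are formed. This
micro-averaging is asserted against a brute-force per-pair counter in the
tests; it is not the mean of per-document scores. A response that maps to
no vocabulary entry can never match a gold preferred name and counts as a
false positive in its category. A response string that is a shared synonym
of several entries resolves to the first entry in vocabulary file order,
with a warning. Categories are scored independently; the combined figure
is the arithmetic mean of the per-category F-scores. All three metrics are
reported in percent.

## Numerical and degenerate-input choices

* Offsets everywhere are 0-based, end-exclusive, in code points.
* A phrase that canonicalizes to zero tokens (empty or all stop words) is
  a valid empty form that matches nothing.
* The approximate threshold is strict (`score > threshold`), so raising it
  is monotone: the match set never grows.
* Overlapping survivors of one category resolve leftmost-longest;
  annotation order ties break by position in the match list, which is
  deterministic.
* Standoff serialization is canonical (tab after the id, single spaces
  between body fields, `T`/`E`/`M`/`R`/`*Equiv` blocks in numeric id
  order), so read-then-write is byte-stable and usable as an equality
  oracle.
* Unknown standoff line types are rejected by default to surface corpus
  dialect issues early; lenient mode downgrades them to warnings.
  Discontinuous (`;`-separated) spans and `N`/`A` lines are out of scope
  and rejected.
* In the BioC layer, infons serialize in stored order, infon keys must be
  unique within an element, and a dangling node `refid` is a validation
  error on write but only a warning on read (so damaged files can still be
  inspected; `validate_bioc()` returns the full violation record).

## Known limitations

Trained CRF sequence labelling, part-of-speech tagging and chunking are
delegated to external toolkits — this package produces their training
input (BIO files) and consumes their output (chunk spans), nothing more.
BioC JSON, XMI and RDF serializations are not supported. Abbreviation
expansion and cross-sentence matching are absent. The evaluation module
scores categories independently and does not attempt cross-category credit
for responses that normalize into a different category than predicted.
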
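# bioconc

Interoperable biomedical annotation formats and dictionary-based concept
recognition for R.

Biomedical text-mining components only compose when they agree on how
annotations are represented. `bioconc` implements two halves of that
problem:

1. **A format layer.** Parsing and serialization of the BioNLP
   shared-task standoff format (document text in `.txt`, annotations as
   plain-text `T`/`E`/`M`/`R`/`*Equiv` lines in `.a1`/`.a2` files) and of
   BioC XML collections, plus a lossless transcription between the two.
   Entities and event triggers become BioC `<annotation>` elements; events,
   equivalence groups and coreference chains become `<relation>` elements;
   `type` infons disambiguate the kinds; `typeUri` infons
   (`uima:ts:` + qualified type name) make elements semantically
   self-describing; negation/speculation modifications become boolean
   infons; coreference links sharing a subject merge into one relation.
2. **A concept-recognition stack** of the kind used for Comparative
   Toxicogenomics Database (CTD) curation support: case-insensitive exact
   dictionary matching, approximate matching by stemmed-token overlap,
   silver-standard corpus generation filtered against per-document gold
   concept lists, BIO token labelling for external CRF toolkits,
   normalization of responses to preferred vocabulary names, multilabel
   action-term assignment from verb-lexicon features, and concept-level
   micro-averaged precision/recall/F evaluation.

The approximate matcher canonicalizes phrases by case folding,
tokenization, stop-word removal, stemming (Porter plus a trailing-`i`
reconciliation rule, iterated to a fixpoint) and token reordering, then
scores phrase–entry pairs by the number of common tokens:

```
"injured by stun gun"  ->  [gun, injur, stun]
"Stun Gun Injury"      ->  [gun, injur, stun]   overlap score = 3
```

Micro-averaged evaluation sums tp/fp/fn over all documents per category
before forming P = 100·tp/(tp+fp), R = 100·tp/(tp+fn) and their harmonic
mean F; the combined figure is the arithmetic mean of the per-category
F-scores.

Audience: developers of biomedical text-mining pipelines who need the two
formats to interoperate, and anyone reproducing a dictionary + silver
-corpus recognition setup without the original web services.

## Worked example

Transcribing standoff annotations (an entity, an event with a speculation
modification) into BioC:

```r
library(bioconc)

txt <- paste0(strrep(" ", 19),
              "interferon regulatory factor 4 xxxx expression")
ann <- paste("T1\tProtein 19 49\tinterferon regulatory factor 4",
             "T11\tGene_expression 55 65\texpression",
             "E2\tGene_expression:T11 Theme:T1",
             "M1\tSpeculation E2", sep = "\n")
doc <- read_standoff(txt, ann, doc_id = "example")
doc
#> standoff_document 'example': 65 chars, 2 text-bounds, 1 events,
#>   1 modifications, 0 equiv groups, 0 corefs
cat(write_bioc(bionlp_to_bioc_collection(doc)))
```

The relevant part of the XML (note `length="30"` for the 19–49 span, the
derived trigger id, and the modification flags):

```xml
<annotation id="T1">
  <infon key="typeUri">uima:ts:uk.ac.nactem.bionlpst.Entity</infon>
  <infon key="type">Entity</infon>
  <infon key="category">Protein</infon>
  <location offset="19" length="30"/>
  <text>interferon regulatory factor 4</text>
</annotation>
<annotation id="TRIGGER_55_65">
  ...
  <location offset="55" length="10"/>
  <text>expression</text>
</annotation>
<relation id="E2">
  ...
  <infon key="category">Gene_expression</infon>
  <infon key="negation">false</infon>
  <infon key="speculation">true</infon>
  <node refid="TRIGGER_55_65" role="EventTrigger"/>
  <node refid="T1" role="Theme"/>
</relation>
```

Silver-annotating a document against a vocabulary and its gold concept
list, then evaluating:

```r
df <- data.frame(concept_id = c("C010", "C020", "D001"),
                 category = c("chemical", "chemical", "disease"),
                 preferred_name = c("lead", "aspirin compound",
                                    "Stun Gun Injury"))
df$synonyms <- list(character(), "acetylsalicylic acid", character())
v <- vocabulary(df)

text <- paste("High doses lead to aspirin compound accumulation.",
              "Patients injured by stun gun recovered.")
gold <- gold_concept_list("doc1", list(chemical = "aspirin compound",
                                       disease = "Stun Gun Injury"))
sd <- silver_annotate("doc1", text, v, gold)
sd$annotations
#>   begin end                text concept_id category score        mode
#> 1    19  35    aspirin compound       C020 chemical     2       exact
#> 2    59  78 injured by stun gun       D001  disease     3 approximate
```

The ambiguous chemical `lead` was matched by the exact matcher but
filtered out — it does not normalize into the document's gold chemical
list. The inflected disease mention (`injured by stun gun` for the curated
`Stun Gun Injury`) was recovered by the approximate matcher with overlap
score 3. Downstream:

```r
head(emit_bio(sd, "chemical"), 6)
#> "High\t0\t4\tO"  "doses\t5\t10\tO"  "lead\t11\t15\tO"  "to\t16\t18\tO"
#> "aspirin\t19\t26\tB"  "compound\t27\t35\tI"
micro_prf(list(gold),
          list(responses_to_concepts("doc1", sd$annotations, v)), v)
#>  category tp fp fn precision recall f_score
#>  chemical  1  0  0    100.00 100.00  100.00
#>   disease  1  0  0    100.00 100.00  100.00
#> combined average F: 100.00
```

A command-line veneer over the same functions ships in
`inst/exec/bioconc` with subcommands `convert`, `match`, `silver`,
`actions`, `eval` and `fixtures`.

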
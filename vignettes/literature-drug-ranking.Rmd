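---
title: "Ranking and augmenting drug sets from literature co-mentions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking and augmenting drug sets from literature co-mentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comention)
```

## The problem

Millions of abstracts co-mention small molecules with diseases, genes,
side effects and other biomedical concepts. `comention` turns that
co-occurrence structure into a drug-prioritization pipeline: given any
search term, it returns (i) a ranked table of drugs already associated
with the term in the literature, and (ii) a ranked table of *additional*
drugs predicted to be related, obtained by seeding drug–drug similarity
matrices with the top literature hits. Everything runs offline against
local tables, so the whole pipeline — including its own benchmark — is
reproducible and testable.

## The model

### Association scoring

The inputs are a drug–PMID table (each drug mapped to the PubMed IDs
that mention it; drugs require at least two supporting PMIDs to enter
the table) and a term query resolved to a PMID set $P_t$ by exact
AND/NOT set algebra over a local (PMID, term) corpus. For each drug $d$
with publication set $P_d$:

$$c_d = |P_t \cap P_d|, \qquad
  f_d = \frac{c_d}{|P_d|}, \qquad
  s_d = c_d \cdot f_d = \frac{c_d^2}{|P_d|}.$$

The count $c_d$ rewards frequently co-mentioned drugs; the normalized
fraction $f_d$ rewards drugs whose literature is *specific* to the term;
the product $s_d$ balances the two and is the default ranking key. The
top $k$ drugs form the **unweighted drug set** (a set, not a weighted
vector). Ties are broken score-desc, count-desc, then name-asc so output
is identical across platforms.

### Augmentation

Two drug–drug similarity matrices drive predictions:

* **co-mention**: $M_{ij} = |P_i \cap P_j|$, pairwise shared-PMID counts
  (diagonal = per-drug totals, never used in scoring);
* **signature cosine**: $M_{ij} = \langle v_i, v_j\rangle /
  (\|v_i\|\,\|v_j\|)$ over drug-induced expression signatures, which are
  taken as given — any z-scoring or characteristic-direction processing
  is upstream of this package. Zero-norm signatures are dropped with a
  warning rather than aborting a whole matrix build.

Candidates are ranked by mean similarity to the seed set. In `predict`
mode seed members are excluded from the output (associated and predicted
compounds are separate tables). In `loo` mode — used only by the
benchmark — every drug is scored and a seed member's own similarity is
excluded from its mean (divisor $m-1$): counting the self term would
trivially inflate every seed member's rank through the diagonal.

### Benchmark

For each term in a GMT library the pipeline runs end to end (query →
associate → top-$k$ set), the matrix ranks all drugs by leave-one-out
mean similarity, and the **positives are the unweighted drug set
itself** — the library contributes only its term list. This mirrors the
evaluation design of literature-based augmentation tools; it asks "does
the matrix recognise that the literature-derived set belongs together?",
not "does it recover the library's curated annotations". Per term we
report AUROC (midrank/Mann–Whitney formulation, ties count ½) and
average precision. The null reference applies one uniformly random
permutation jointly to the matrix's row and column labels — the value
grid, its symmetry and spectrum are untouched; only the drug identities
are scrambled — pooled over `n_shuffles` (default 10) permutations.
Observed and null per-term distributions are compared with a two-sided
Mann–Whitney U test (exact enumeration when $n_1+n_2 \le 16$ without
ties; otherwise normal approximation with tie and continuity
correction).

## The synthetic world

`generate_world()` emulates the statistical structure the scorer
exploits, with no real text: each publication is about exactly one term;
a publication mentions each of its term's planted drugs with probability
`p_planted` and every drug with background probability `p_background`;
planted co-term drugs additionally share an expression-signature cluster
(centroid + isotropic noise, `cluster_noise_sd`). Defaults — 200 drugs,
20 terms, 5,000 publications, 10 planted drugs per term, `p_planted =
0.3`, `p_background = 0.01`, 100 genes, noise SD 0.5 — are the standard
study conditions used by the test suite and the acceptance script. The
one-term-per-publication simplification keeps the generative model
transparent while preserving the co-mention signal; multi-topic
documents, realistic abstract language, name synonymy and the heavy
tails of real drug-literature coverage are deliberately *not* modelled,
so passing tests demonstrate correctness of the machinery and
recoverability of planted signal, not performance on PubMed.

```{r}
world <- generate_world(planted_world_config(rng_seed = 1))
term <- names(world$library)[1]
assoc <- associate(world$rif, query_pmids(world$corpus, term))
head(assoc)
recovery_rate(assoc, world$truth, term, k = 10)
```

## Parameters that matter

* `min_pmids` (default 2): evidence floor per drug; raising it shrinks
  the table monotonically.
* `k` (default 20, pipeline range 20–200): unweighted set size. Larger
  `k` admits weaker literature hits into the seed, diluting both
  augmentation and benchmark positives. The benchmark in the acceptance
  script uses `k = 10`, matched to the planted-set size so that seed and
  ground truth are commensurate.
* `rank_by`: `score` (default), `count` (favours heavily studied drugs)
  or `fraction` (favours niche-literature drugs).
* `top_n` (default 20): predictions reported per matrix.
* `n_shuffles` (default 10): null permutations pooled per term; more
  shuffles smooth the null at linear cost.

## Numerical and design choices

* Exact integer arithmetic everywhere in association scoring; `score`
  is reported at full precision and only rounded (6 significant digits)
  in TSV exports.
* Cosine matrices are symmetrized (`(M + t(M))/2`) and clipped to
  $[-1, 1]$ to absorb floating-point round-off; asymmetry beyond 1e-8
  on construction is an error, and serialization round-trips are exact
  to reader precision.
* Label order is ascending C-locale (radix) sort at construction;
  readers preserve file order. All ties anywhere break by ascending
  drug name.
* Degenerate inputs: empty query results are a success (empty tables +
  warning), not an error; an all-constant matrix yields AUROC 0.5 for
  every term and a Mann–Whitney p of 1 (zero variance is caught
  explicitly).
* Average precision depends on tie order; the deterministic name-asc
  tie-break makes it reproducible, and the AUROC uses midranks so it is
  tie-order invariant.
* The run manifest records version, parameters, seed and input MD5
  checksums but no timestamps, keeping identical invocations
  byte-identical.

## A calibration caveat the benchmark itself reveals

In a signal-free world (`p_planted = p_background`) the benchmark over
the **signature** matrix is exactly calibrated: observed and null AUROC
distributions coincide and the shuffle test rejects at close to its
nominal rate. Over the **co-mention** matrix it is anti-conservative
*by construction*: the seed set and the matrix derive from the same
corpus, so drugs selected into a seed by chance co-occurrence with the
term's publications also share more PMIDs with each other than random
pairs do. The package's tests pin both facts. The practical reading:
significance of a co-mention-matrix benchmark against its shuffle null
overstates the evidence; the signature channel, built from an
independent data modality, supports the calibrated comparison.

## Problem sizes

The test suite and acceptance script run worlds of 40–200 drugs and
400–5,000 publications with 2–10 null shuffles — sizes chosen so the
planted signal is unambiguous while a full run stays in the minutes
range on one core. The implementation itself (sparse incidence products,
vectorised scoring) handles the tens-of-thousands-of-drugs scale of real
literature tables; a dense 20k × 20k similarity matrix is ~3 GB in
double precision, so serialized matrices can be stored gzipped and read
back transparently.

## Known limitations

* Retrieval semantics are exact-match set algebra; MeSH expansion,
  fuzzy matching and PubMed query syntax are out of scope.
* Similarity fusion across the two matrices is not attempted; they are
  reported side by side.
* The co-mention benchmark's circularity (above) is a property of the
  evaluation design, inherited knowingly; treat its p-values as
  descriptive.
* Weighted seed sets are not supported; the seed is a set by design.
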
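---
title: "Weighted-voting consensus of per-read taxonomic classifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-voting consensus of per-read taxonomic classifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxvote)
```

## The problem

Database-bound taxonomic classifiers disagree: run eight of them over the
same shotgun reads and each read collects up to eight different taxids,
emitted at heterogeneous depths (one tool says *E. coli* O157:H7, another
says *Escherichia*, a third abstains). `taxvote` treats this disagreement
as signal. Each tool casts a weighted vote per read; after projecting every
vote to a common rank, the label with the highest aggregate weight becomes
the consensus. Two variants trade recall against precision:

* **merge** (high recall) drops abstentions from the tally, so a single
  confident tool can classify a read the others gave up on;
* **merge_p** (high precision) lets abstentions vote too, pooled under an
  UNKNOWN candidate, and calls the read *unknown* when that candidate's
  aggregate weight beats every taxon **strictly**. This is what protects
  against organisms absent from all reference databases: when most tools
  abstain (or scatter), UNKNOWN wins and no false taxon is reported.

## The model, precisely

Let tool $t$ have weight $w_t \ge 0$ and emit label $x_t(r)$ for read $r$.
With projection $\pi_\rho$ to target rank $\rho$, the tally is
$W(c) = \sum_{t\,:\,\pi_\rho(x_t(r)) = c} w_t$ over candidates $c$ (taxa,
plus UNKNOWN under merge_p). The verdict is $\arg\max_c W(c)$ with these
declared rules where the argmax is not unique or not meaningful:

* an empty tally (merge with all tools abstaining) is UNCLASSIFIED;
* under merge_p, UNKNOWN must win strictly; on a tie with a taxon, the
  taxon prevails — "the aggregated unknown weight is high" is thereby
  operationalized as a strict argmax, the most conservative reading that
  needs no extra threshold parameter;
* taxa tied at the maximum collapse to their lowest common ancestor, and a
  root-level LCA degrades to UNCLASSIFIED. This tie rule is deterministic,
  order-free, and never invents precision the votes do not support;
* tools with weight 0 contribute nothing, not even to UNKNOWN.

Projection $\pi_\rho$ replaces a taxid by its ancestor at rank $\rho$,
walking through unranked ("no rank") nodes transparently; a label whose own
rank is already broader than $\rho$ projects to UNCLASSIFIED. Votes are
projected *before* tallying because tools emit mixed depths — otherwise a
species-level consensus would fragment across a species and its strains.
Raw-taxid voting remains available (`project = FALSE`).

Two further declared choices: a read absent from one tool's output file is
that tool's unclassified vote (the formats give no way to distinguish the
two, and under merge the two readings coincide anyway); and a stricter
unanimity variant of merge (`require_unanimity = TRUE`, off by default)
blanks reads whose classified votes disagree, for users who read
"unanimously agreed upon" literally.

### Weights

Weights default to 1 (equal voting). `fit_weights()` implements the
documented intent that weights derive from performance indicators measured
on a *separate* tuning set: each tool's weight is its accuracy at the
target rank, normalised so the best tool gets 1 (all-zero accuracies fall
back to equal weights with a warning). The exact weighting used in the
original study is unpublished; accuracy-proportionality is this package's
declared stand-in, and weights are always explicit inputs — `merge_all()`
never fits them implicitly.

## Evaluation scheme

Simulated reads all have a known source organism, so classical true
negatives do not exist. At rank $\rho$, with both prediction and truth
projected:

| outcome | condition |
|---|---|
| TP | in-reference read, projected prediction = projected truth |
| FN | in-reference read, prediction unclassified/unknown |
| FP | any read assigned to a wrong taxon |
| TN | out-of-reference read, prediction unclassified/unknown |

and the four metrics are accuracy $=(TP+TN)/n$, precision $=TP/(TP+FP)$,
recall $=TP/(TP+FN)$, and the **modified FPR** $=FP/n$ — the fraction of
all evaluated reads sent to a wrong taxon. With no out-of-reference reads
this reduces exactly to the TN-free accounting (TN $= 0$ always). Zero
denominators make precision/recall *undefined* (serialized `null`/`NA`),
never 0: a tool that abstains on everything must not score a 0 precision
that averages as if it had been measured. Out-of-reference reads make TN
attainable; whether abstention on such reads should instead be excluded
from accuracy is not documented anywhere we could follow, so the
generalized table above is a declared choice, not an inference.

## What the simulator emulates — and what it does not

The generator restates the benchmark design it stands in for: **30
species**, of which **3 (10%) are flagged out-of-reference**, i.e. absent
from every simulated tool's reference database; reads drawn uniformly (or
log-normally) across species; and **eight heterogeneous tools** whose error
profiles mix correct calls, over-specific subspecies calls, sibling
misassignments within the genus, distant misses outside it, and abstention.
Out-of-reference reads are special-cased: a database-bound tool cannot name
a species its database lacks, so it abstains with probability
`oor_abstain_prob` and otherwise asserts a uniformly random in-reference
species — the failure mode that makes consensus precision collapse on
unknown organisms and motivates merge_p.

Default taxonomy: two superkingdoms (mirroring a bacteria-plus-fungi pool),
branching down to 10 genera of 3 species each, every species with one
subspecies child so over-specific calls are expressible. One master seed
plus a fixed per-tool offset (`(master_seed + 100003 * offset) mod 2^31`)
makes every artifact byte-reproducible. Default `n_reads` is 10,000 —
large enough for stable frequencies, small enough for test budgets.

Not emulated, deliberately: sequence-level simulation (read lengths,
coverage, Illumina error models — classifier *outputs* are simulated, not
reads), any real classifier's decision process, database construction, and
the original 240-dataset factorial grid (a replicate count stands in for
it). A green test therefore establishes that the voting and scoring
machinery is correct and that ensemble gain holds under conditionally
independent error profiles; it says nothing about how correlated real
classifiers' databases make their errors — the known limitation of any
consensus of database-bound tools, which share blind spots.

## Numerical choices

* Tally comparisons are exact floating-point comparisons; verdicts are
  invariant to positive rescaling of all weights and to tool order (the
  tie rule is symmetric), both asserted exactly in the test suite.
* Profile probabilities must sum to 1 within `1e-9`.
* Output files are deterministic: rows sorted by read id (radix), fixed
  `%g`-style number formatting, so reruns are byte-identical.
* Taxids absent from the loaded taxonomy demote to UNCLASSIFIED with a
  warning by default (tool databases and taxonomy dumps drift); a strict
  mode errors instead. Merged/deleted-taxid remapping is out of scope.

## Worked run

```{r, eval = FALSE}
cfg   <- simulation_config()
tree  <- simulate_taxonomy(cfg)
truth <- simulate_truth(tree, cfg)
outs  <- simulate_tool_outputs(tree, truth, default_tool_profiles(), 1)
res   <- merge_all(outs, strategy = "merge_p", tree = tree)
evaluate_many(c(outs, list(res$consensus)), truth, c("species", "genus"), tree)
```

The README shows the numbers this prints under seed 1; the acceptance
suite (`tests/testthat/test-acceptance.R`) asserts the properties behind
them: verdict-level equivalence with a brute-force tally enumerator,
containment of merge_p's assignments in merge's, the no-error limit, and
ensemble accuracy above the best single tool in at least 95% of 50
replicates at $p_{correct} = 0.8$.
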
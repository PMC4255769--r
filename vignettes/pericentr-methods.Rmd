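---
title: "Inferring pericentric inversions from chromosome-arm assignment patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring pericentric inversions from chromosome-arm assignment patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pericentr)
library(dplyr)
```

## The model

Allohexaploid bread wheat carries three related subgenomes (A, B, D).
Most genes exist as homoeologous triplets, one copy per subgenome, and in
the unrearranged state the three copies sit on mutually homoeologous
chromosome arms: for groups 1, 2, 3, 5, 6 and 7 these are simply the
three short arms and the three long arms. Group 4 is the standing
exception: the ancient 4A/5A/7B cyclic translocation and the associated
inversion history reversed the homoeology of chromosome 4A's arms, so the
expected sets are 4AL/4BS/4DS and 4AS/4BL/4DL (`expected_homoeology()`),
and the modern 4A is a mosaic of ten ordinal segments from four ancestral
arms (`build_4a_model()`).

A *pericentric* inversion has one breakpoint on each arm, so it carries a
block of genes across the centromere. If shotgun sequence is available
per flow-sorted chromosome arm, the arm location of each copy of a gene
is observable, and a gene inside exactly one homoeologue's inversion
shows a *nonstandard* triplet (e.g. 1AS/1BL/1DL). The method therefore
reads rearrangement off arm-location patterns alone: it needs no
assembly, but it is blind to paracentric inversions, and it attributes
each nonstandard triplet to the *minority* copy — when two homoeologues
moved, the standard-looking copy is blamed instead (that asymmetry is
inherent to the pattern evidence, not an implementation choice).

## Pattern classification

`classify_arm_patterns()` consumes standard 12-column BLAST tabular hits
whose subjects are arm libraries ("1AL" ... "7DS") or the
whole-chromosome library "3B". The steps, with the reasoning for each
operationalization:

* **E-value threshold** (default `1e-5`, configurable): applied before
  any ranking.
* **Best HSP per library, total ranking.** Multiple HSPs on one arm
  library collapse to the best one; libraries are then ranked by
  descending bitscore with ties broken by ascending e-value, descending
  identity, then lexicographic library id. The tie-break chain carries no
  biological meaning; it exists so that identical inputs yield
  byte-identical outputs. (Ranking all HSPs instead of the best per
  library is the documented alternative; it would let one repetitive arm
  crowd out the other homoeologues.)
* **3B coordinate rule.** 3B hits are assigned by their midpoint on the
  pseudomolecule: below 265 Mb → 3BS, above 387 Mb → 3BL, inside the
  centromeric interval → dropped before triplet formation. Boundary
  positions count as inside, the conservative reading. The midpoint is a
  deterministic stand-in for "where the gene is" given that only hit
  coordinates are available.
* **Both-arm exclusion.** A minute centromeric region can be present in
  both telosomic arm libraries of one chromosome, so a gene whose
  location-determining (top-3) hits include both arms of a chromosome has
  an undecidable arm of origin and is excluded. The exclusion is
  deliberately restricted to the top three hits: deeper-ranked
  opposite-arm hits are the business of the secondary check below — if
  any opposite-arm hit anywhere in the table excluded the gene, the
  secondary inspection would have nothing left to inspect.
* **Top-3 homoeology rule.** The three best hits must fall on the three
  chromosomes of one group, one per subgenome. A triplet equal to an
  expected set is `standard`; otherwise the copy disagreeing with the
  expected set matched by the other two names the inferred transfer
  (`"1DL->1DS"`). Fewer than three hits → `excluded_incomplete`; top
  three spanning groups → `excluded_top3_not_homoeologous`.
* **Secondary-hit flag.** For nonstandard genes, hits ranked 4–10 on the
  opposite arm of a triplet chromosome with bitscore within `delta`
  (default 10 % of the rank-3 score) mark the gene
  `flagged_ambiguous_secondary`. This automates what was historically a
  visual inspection; it flags, and never auto-excludes, so that accept
  and exclude counts are unaffected while ambiguity is surfaced. Strict
  mode in the caller drops flagged genes from the evidence counts.

## Inversion calling

`call_inversions()` aggregates accepted nonstandard genes per chromosome
and applies three criteria for **strong** evidence of a pericentric
inversion: at least 6 transferred genes in total; both directions
represented with at least 3 genes each; and the co-mapping criterion —
at least one short-arm locus and one long-arm locus within `epsilon` cM
(default 2.0 cM, configurable; the underlying idea is "co-located or
tightly linked", which has no unique numeric form). Because wheat
recombination is strongly suppressed around centromeres, genuinely
pericentromeric loci collapse to nearly a single map position, so the
default tolerance is forgiving without being vacuous.

A chromosome with 11 or more transferred genes but essentially one-sided
direction evidence (minority direction < 3) is a **putative** inversion.
The two classes are disjoint by construction. Whether the putative class
should also demand map evidence is genuinely open; we require none, since
one-sided evidence cannot demonstrate centromere encompassment anyway.

Chromosome 3B is called like any other chromosome but carries a warning:
its arm assignments rest on pseudomolecule scaffold placement, and
misplaced scaffolds mimic transfers. A count-only entry path
(`call_inversions_from_counts()`) exists for published tallies; it
requires the caller to state the assumed co-mapping outcome, because
counts alone cannot decide a chromosome like 1B (3 + 3 transfers whose
loci may or may not co-map).

## Single-genotype combinatorics

An inversion configuration assigns each homoeologue a present/absent
state and two breakpoint depths (distance from the centromere, one per
arm). Only comparisons between probe depth and breakpoint depths matter,
so depths are discretized to ranks 0–3 per arm side and probes placed at
interval midpoints exhaust the behaviour space; ties between breakpoints
merely merge intervals and are included in the search. A probe on an
ancestral arm set moves on exactly the homoeologues whose inversion
spans it; a probe moved on all three appears standard again. Patterns
are compared as observable triplet strings, so coincidences between
short-origin and long-origin probes count once.

Exhaustive search over every subset of inverted homoeologues crossed
with every rank assignment (`max_nonstandard_patterns()`) gives a
maximum of **four** distinct nonstandard triplets, matching the closed
form `closed_form_max(k) = 2 * min(k, 2)` for `k` inverted homoeologues —
each arm side contributes at most two nonstandard nested breakpoint
subsets because the all-three subset is standard-appearing. The two
routes are independent and tested against each other. The engine is
label-invariant: running it under the group-4 expected sets yields the
same counts. One modelled assumption deserves emphasis: *one* pericentric
inversion per homoeologue. Whether stacked sequential inversions on one
chromosome could exceed four patterns is outside the modelled space.

`feasibility_check()` searches the same canonical space for a witness
configuration reproducing an observed pattern set; five or more distinct
nonstandard patterns in one group are infeasible, which is the logical
backbone of the argument that some observed rearrangements arose during
aneuploid stock production rather than in the euploid genotype.

## Deletion-bin reconciliation

Bin labels are parsed structurally (`C-` prefix = centromere-anchored,
interval from 0; otherwise an explicit fraction interval). Both hyphen
and en-dash are accepted as interval separators and the bin number may or
may not be preceded by a hyphen, because published labels mix all these
forms. The decision rule: same arm → concordant; opposite arm with a
centromere-anchored bin and no ditelosomic-line evidence →
`uninformative_pericentromeric` (a pericentromeric bin location is
concluded when a fragment is present in all deletion lines, which cannot
tell a pericentromeric short-arm from a long-arm location); opposite arm
otherwise → contradicts. Ditelosomic evidence availability is an input
column — it historically required scrutinizing autoradiographs, which is
not automatable — and defaults to available.

## The synthetic genome

`simulate_genome()` is the stand-in for flow-sorted chromosome-arm
shotgun data, and its defaults are the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| genes per group | 200 | enough for ~25 genes per planted inversion side |
| centromere position | 0.5 of chromosome | metacentric idealization |
| pericentromeric fraction | 0.3 of each arm | broad low-recombination region, as in wheat |
| suppressed recombination density | 0.02 of distal | compresses pericentromeric loci to ≪ 2 cM |
| map length | 150 cM | wheat-like chromosome map |
| gene loss rate | 0.05 | loss is common in polyploid wheat; no published per-subgenome rate, implementer choice exposed in config |
| duplication rate | 0.10 | duplications about twice as common as losses, same caveat |
| decoy hit rate | 0.05 | off-group hits that occasionally displace a homoeologue |
| homoeologue identity | N(97, 1.5) % | subgenome divergence scale; only rank order matters downstream |

Placement: each gene triplet gets an ancestral arm side and a depth
drawn uniformly; copies sit on the arm their homoeologous set predicts
(the group-4 swap applies on 4A). Euploid inversions relocate copies
with depth shallower than the breakpoint to the opposite arm; the
relocated depth is rescaled into the opposite breakpoint region
(order-preserving) rather than strictly reversed — a strict geometric
reversal with unequal breakpoint depths would also move the centromere
and leave some spanned genes on the same arm, complexity that changes
nothing observable downstream (arm identity, compressed cM, truth
labels). The default 4A placement encodes only the arm swap; the
ten-segment mosaic is ordinal knowledge in the homoeology model, not a
base-pair layout, because segment extents are not part of the model.

Aneuploid artifacts model the hypothesis that producing telosomic
stocks restructured pericentromeres: each artifact is an extra
pericentric inversion in the aneuploid source line of *one* arm library,
applied after the euploid structure. Because every arm library comes
from its own line, an unmatched artifact makes genes appear in both or
neither arm library of a chromosome (which the classifier duly excludes);
listing the same artifact for both arm libraries of a chromosome models
a double-ditelosomic source line seen consistently by both libraries,
and composing it with a euploid inversion on the same chromosome turns
the moved set into an annulus — which is how a genome escapes the
four-pattern bound. The documented escape configuration (euploid
inversions on 6B and 6D plus a matched shallower artifact on 6D)
produces six distinct nonstandard patterns, and `feasibility_check()`
correctly rejects the set.

The truth table carries per-copy moved/lost/duplicated flags *and* the
derived per-gene observable triplet, because the two deliberately
diverge when several homoeologues move (the standard-appearing case);
recovery tests compare the classifier against the observable truth,
which equals the moved set whenever at most one homoeologue per group is
inverted.

3B is emitted as a whole-chromosome library with pseudomolecule
coordinates (774 Mb, centromere 265–387 Mb) so the coordinate→arm rule
is exercised end to end. Hits carry a simple identity-derived bitscore;
no nucleotide-level evolution is simulated — sequence realism is not the
simulation substrate, rank order is.

## What passing tests do and do not show

The simulator emulates the *structure* of arm-resolved hit data: triplet
homoeology, the group-4 swap, planted rearrangements, recombination
suppression, loss/duplication/decoy noise, and the 3B special case. It
does not emulate repeat-driven spurious alignment, assembly artifacts,
uneven arm-library coverage, or realistic score distributions. Parameter
recovery on simulated data therefore validates the pipeline's logic and
determinism, not the error profile to expect on real shotgun data — on
real data the classification thresholds (e-value, `delta`) and the
co-mapping tolerance carry the weight, and the published per-chromosome
count table is included (`cs_rearrangement_counts()`) precisely so the
report path can be exercised against real-scale numbers.

Problem sizes used by the test suite and the acceptance script — 60–300
gene triplets per group in unit tests, 200 per group with 25 replicate
genomes for noisy recovery — were chosen to give stable counts (~50
transferred genes per planted inversion) at desk scale.

## Known limitations

* Paracentric inversions are invisible to arm-location patterns.
* Transfer direction is attributed to the minority copy; with multiple
  inverted homoeologues the attribution can be wrong even though the
  nonstandard call itself is correct.
* `build_ortholog_set()` implements cross-source reciprocal-best-hit
  clustering with source priority; it treats within-source reciprocal
  pairs as input errors rather than merging them.
* The feasibility engine assumes at most one pericentric inversion per
  homoeologue (see above).
* Breakpoint localization in base pairs is out of scope; calls are
  per-chromosome verdicts with supporting genes.
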
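---
title: "Building, assessing and using probabilistic functional gene networks"
author: "cofunet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building, assessing and using probabilistic functional gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofunet)
```

## The model

A functional gene network is an undirected weighted graph whose edge
weights express confidence that two genes participate in the same
biological process. `cofunet` covers the full life cycle of such a
network: constructing the training labels, calibrating heterogeneous
evidence into a common probabilistic currency, integrating evidence layers,
benchmarking the result, and using it to nominate candidate genes for a
phenotype.

### Gold standard and prior odds

Given flat pathway annotations (GMT), the positive set contains every
unordered pair of distinct genes co-annotated to at least one term; the
negative set contains every remaining pair of annotated genes. The two
sets partition all $\binom{G}{2}$ pairs of the annotated universe, so
their ratio defines the prior odds $P/N$ of co-functionality. The negative
definition is the standard complementary construction: annotations assert
positives, and pairs of annotated genes that never co-occur are the most
defensible proxy for non-co-functionality.

Two filters guard the standard. `filterBroadTerms()` removes terms larger
than a configurable size cap *before training*, because broad concepts
(e.g. "metabolic process") generate quadratically many co-annotated pairs
and would dominate calibration; the cap is deliberately a knob rather than
a fixed rule, since what counts as "broad" depends on the annotation
source. `dropLargestTerms()` removes the top-$n$ largest terms *before
validation* so that assessment is not driven by a handful of huge terms;
$n = 20$ is the conventional choice for genome-scale GO validation sets.

### Log-likelihood calibration

For one evidence layer, pairs carrying a gold label are sorted by raw
score (descending) and cut into contiguous bins, each holding at least
`minPosPerBin` positives (default 100). Equal-positive-count binning keeps
the sampling variance of each bin's estimate roughly constant; the default
of 100 positives bounds the LLS standard error near
$\sqrt{1/pos + 1/neg} \lesssim 0.15$. A bin never splits a run of tied raw
scores, which makes the cut deterministic. Each bin scores

$$LLS = \ln\frac{(pos + c)/(neg + c)}{P/N},$$

with the Haldane–Anscombe pseudocount $c = 0.5$ by default so zero-count
bins stay finite. No monotonic smoothing is applied across bins: imposing
isotonicity would assume the evidence score is monotonically informative,
which is structure the calibration should reveal, not presuppose.
`scoreComponent()` then assigns every pair its bin's LLS; terminal bins
are open ($\pm\infty$), so out-of-range raw scores take the nearest
terminal bin rather than being dropped silently. Pairs with
$LLS \le$ `minLLS` (default 0: no better than the prior) are excluded
from the component network.

### Weighted-sum integration

A pair observed in several layers with per-layer values
$L_0 \ge L_1 \ge \dots \ge L_{n-1}$ integrates to

$$WS = L_0 + \sum_{i=1}^{n-1} \frac{L_i}{D \cdot i},$$

where $D \ge 1$ degrades lower-ranked evidence, compensating for
correlation between layers (fully independent Bayesian evidence would sum
freely, $D = 1$; $D \to \infty$ trusts only the single best layer).
Because the upstream method fixes $D$ without publishing it, `cofunet`
defaults to the neutral $D = 1$ and offers `selectD()`, a grid search that
maximizes the area under the odds-ratio-versus-recall curve on held-out
gold pairs, breaking ties toward the smaller (less aggressive) value. Ties
among equal LLS values are ordered by component input position, which
makes integration deterministic and invariant to permuting the component
list.

## Assessment

`prCurve()` walks the network's links from the highest score down and
reports cumulative recall and the odds ratio

$$OR = \frac{pos_{in} / neg_{in}}{pos_{tot} / neg_{tot}},$$

precision relative to chance among validation-labeled links. Only labeled
links enter the counts — the printed definition is a ratio of label
counts, so unlabeled links carry no information about either count. Tied
scores are processed as one block, otherwise the curve would depend on an
arbitrary ordering within ties. With no continuity correction an
all-positive prefix yields an infinite OR, reported as `Inf`; a correction
of 0.5 is used internally when a finite curve area is needed (e.g. in
`selectD()`).

Per-term prediction power (`aucPerTerm()`) scores every network gene by
the sum of its edge weights to a term's members (`gbaScores()`) and
summarizes member recovery as the rank-sum AUC with mid-rank tie handling
(`rocAuc()`). A member is scored only against the *other* members
(leave-one-out), since ranking all genes of the network — members
included — would otherwise leak the label being predicted. Terms need at
least five members in the network ("more than four") to qualify.
`compareNetworks()` compares two networks' paired per-term AUC vectors by
the two-sided Wilcoxon signed-rank test; `rankSumCompare()` provides the
unpaired Mann–Whitney analogue used for, e.g., expression of top
candidates versus random genes.

Both Wilcoxon routines are implemented in the package rather than
delegated, because the reference implementation declines exact p-values
under ties, while paired AUC differences and expression values tie
routinely. For $n \le 16$ non-zero differences the signed-rank null is
enumerated over all $2^n$ sign assignments of the mid-ranks; for combined
samples of $\le 20$ the rank-sum null enumerates all
$\binom{n_a+n_b}{n_a}$ labelings. Zero differences are dropped (standard
convention); larger samples use the tie-corrected normal approximation
with continuity correction, which agrees with enumeration to within a few
percent outside the extreme tail (relative agreement necessarily breaks
down as the exact p approaches $2^{-n}$). In tie-free cases both routines
reproduce `stats::wilcox.test` exactly, which the test suite uses as an
independent cross-check.

## Prioritization

**Direct neighborhood** (`neighborhoodRank()`): candidates are the direct
neighbors of the mapped guide genes; each is scored by the sum of its edge
weights to the guides, never by indirect paths. Guides are excluded from
the candidate list (the point is novel genes), and guide-to-guide edges
contribute nothing. Ties are broken lexicographically by gene id, dense
ranks are assigned, and the list is cut after the 100th row by default —
with a note when a tie straddles the cut, since the served cut is then one
of several defensible choices.

**Context-associated hubs** (`contextHubScan()`): when guide genes are
scarce, condition-specific differentially expressed genes (DEGs) can
substitute. Every gene with more than 50 neighbors (strict reading of the
threshold) defines a subnetwork; the overlap between its neighbors and the
DEG set is tested with the one-sided hypergeometric (Fisher) upper tail
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$. The universe $N$ is
the network's gene set, not the genome: the test asks whether a
*neighborhood* is DEG-enriched, and genes outside the network cannot be
neighbors; DEGs outside the network are dropped with a reported count.
The raw threshold $p \le 0.01$ is the method's operating convention;
Benjamini–Hochberg q-values are opt-in because the scan is a screen whose
hits are validated downstream, not a confirmatory family of hypotheses.

**Orthologous guides** (`reciprocalBestHits()`, `translateGuides()`):
guide genes from a related genome are translated through reciprocal best
hits parsed from 12-column tabular similarity-search output, requiring
$E \le 10^{-4}$ in both directions by default — strict, because closely
related genomes make spurious orthology the dominant risk. Ties in best-hit
selection resolve by E-value, then bit score, then lexicographic target,
making the mapping deterministic; the strict table is asserted to be a
bijection on every run. Inparalog-inclusive one-to-many mappings are
consumed from externally supplied tables; no clustering is implemented.

## Synthetic data and what the benchmarks show

The generators in `plantedModuleNetwork()`, `evidenceTables()`,
`plantedDegContext()` and `hitTableFixture()` are pure functions of their
parameters and a mandatory seed. Bernoulli edges and Gaussian evidence
noise were chosen because their expectations are analyzable — the test
suite checks observed edge counts against binomial moments and fitted LLS
against known per-bin odds ratios within three standard errors.

The end-to-end benchmark plants five 100-gene modules in a 500-gene
universe, generates three evidence layers at signal 2.0 (in noise-SD
units), calibrates, integrates, and measures mean per-term AUC; it then
repeats with the signal halved. Because 100-gene modules are highly
redundant, per-term AUC saturates at 1.0 for both signal levels when the
*entire* integrated network is evaluated; the comparison is therefore run
on size-matched high-confidence cores (top $2n$ links, average degree 4),
mirroring the standard practice of truncating the larger network to the
smaller one's link count whenever two networks are compared. Under size
matching, full signal stays at mean AUC 1.0 and the degraded pipeline is
strictly lower. Problem sizes throughout (hundreds of genes, $10^5$ pairs,
100 hub-scan replicates) were chosen so the whole suite runs in seconds
while keeping the statistical assertions sharp.

What passing these benchmarks does *not* show: real evidence layers are
correlated, non-Gaussian and incomplete; real pathway membership is
overlapping and hierarchical rather than a partition; real DEG sets carry
batch structure no Bernoulli model produces. The synthetic results
validate the *machinery* — calibration recovers known odds, integration
and ranking are deterministic and correctly ordered, the scan finds a
planted signal — not the biological performance of any particular network.

## Numerical conventions and degenerate inputs

- Gene ids are trimmed and upper-cased; pairs are stored once, endpoints
  in lexicographic order; self-pairs are errors everywhere.
- Edge scores are written with 6 significant digits, enough for bit-stable
  text round-trips without false precision.
- Duplicate pairs in input files abort by default (`dedup = "error"`);
  `"max"` merges orientations keeping the larger score.
- `topLinks()` breaks score ties by canonical pair order, so size-capped
  networks are reproducible.
- Empty neighborhoods, absent genes, empty hub lists and empty orthology
  tables return empty results; an evidence layer sharing no pair with the
  gold standard, a DEG set disjoint from the network, or a guide set that
  maps nowhere raise informative errors instead.

## Limitations

- Gold-standard pair sets are materialized in memory as sorted key
  vectors; comfortable to a few thousand annotated genes
  ($\sim 10^7$ pairs), beyond which a streamed construction would be
  needed.
- Annotation terms are flat sets: no ontology-graph propagation.
- The package consumes precomputed evidence pair-scores, DEG lists and
  similarity-search output; it does not compute co-expression, run
  searches, or call differential expression.
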
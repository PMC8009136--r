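---
title: "Models and methods for reductive plastid-genome evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for reductive plastid-genome evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastevol)
```

## The scientific problem

Plastomes of fully heterotrophic plants (mycoheterotrophs, holoparasites)
undergo reductive evolution: photosynthesis genes go first, then tRNA,
rRNA and ribosomal-protein genes are pseudogenized and lost, while the
nucleotide composition drifts toward extreme AT richness. `plastevol`
provides the analyses this regime calls for, exercisable end to end on
synthetic data: quadripartite structure detection, a gene
intact/pseudogene/absent matrix with parsimony mapping of losses,
equilibrium AT-content estimation from ancestrally reconstructed
substitutions, context-resolved synonymous substitution spectra,
branch-model dN/dS contrasts, and Ornstein--Uhlenbeck tests for shifts in
amino-acid composition.

## Equilibrium AT content

Write $[GC]$ for the strong bases and $[AT]$ for the weak ones, and let
$k_1$ and $k_2$ be the per-site frequencies of $[GC]\to[AT]$ and
$[AT]\to[GC]$ substitution. With $N_{GC}$ strong sites, the flux balance
$dN_{GC}/dt = k_2 N_{AT} - k_1 N_{GC}$ vanishes at equilibrium, giving
the equilibrium AT fraction

$$\alpha_{eq} = \frac{k_1}{k_1 + k_2}.$$

Branch duration divides $k_1$ and $k_2$ equally and cancels, so it is
never computed. Per branch, $k_1$ is estimated as the number of observed
$[GC]\to[AT]$ endpoint differences between the ancestral (reconstructed)
and descendant sequences divided by the ancestral $N_{GC}$, and likewise
for $k_2$; sites are used only when the ancestral-indel reconstruction
marks both endpoints present and both states are unambiguous bases.

Two per-species scopes are provided, because published per-species values
can be formed either way: `terminal_branch` (default) uses only the tip's
pendant branch, `clade_path` pools counts from the ingroup root to the
tip. Both are labelled in output; neither is asserted to be "the"
reference convention.

Confidence intervals come from resampling alignment columns with
replacement (the reference analysis uses 1000 pseudoreplicates; tests use
150--200), re-deriving counts per replicate, and taking 2.5th/97.5th
percentiles. Because the marginal reconstruction of a site depends only
on its own column pattern once the model is fixed, per-pattern counts are
computed once and a replicate reduces to reweighting patterns -- exactly
equivalent to re-running the reconstruction per replicate, at a small
fraction of the cost. Model parameters, branch lengths and indel rates
are held at their full-data estimates across replicates, so the CI
reflects counting noise given the fitted model, not refitting noise.

Known bias: endpoint comparison cannot see multiple substitutions at one
site on one branch, a downward bias shared by any analysis that counts on
point reconstructions. MAP reconstruction itself also shrinks counts
toward the model's stationary composition; the effect vanishes as
branches shorten and taxon sampling tightens ancestor estimates. On very
sparse trees it can be severe -- with only two taxa the MAP ancestor of
every variable site collapses to the a-priori more frequent class, so
per-species estimates should always be read with the tree's density in
mind. The simulation checks in the test suite therefore use 8 taxa with
branch lengths of 0.02 substitutions/site, where the residual bias
(about +0.003 on $\alpha_{eq} = 0.75$) is an order of magnitude below the
Monte-Carlo spread.

## Ancestral reconstruction

The likelihood engine is standard Felsenstein pruning over 4 nucleotide
states (or 61 sense codons) with per-site rescaling, GTR exchangeabilities
scaled to GT = 1, rate matrices normalized to one expected event per site
per unit branch length, and equal-probability discrete-gamma rate
categories (category means). Ambiguity codes contribute a partial
likelihood of 1 over their compatible states. Marginal ancestral
posteriors use an inside--outside pass and are averaged over gamma
categories with empirical-Bayes weights (the per-site category
posteriors); MAP ties break in the fixed order A < C < G < T. For
reconstruction the tree is rooted on the midpoint of the outgroup's
pendant branch -- the likelihood is root-invariant under these reversible
models, and downstream counting uses only ingroup branches.

Indels are reconstructed per site with a two-state (present/absent)
continuous-time model whose gain and loss rates are estimated once per
alignment by ML; a node is called present when its marginal posterior
exceeds 0.5. Constant patterns short-circuit (gap-free sites are present
everywhere, all-gap sites absent everywhere). Per-site coding is this
package's documented choice; coding whole indel events would require an
indel model the data formats do not carry.

Model fitting (`fit_gtr`) estimates exchangeabilities, gamma shape and
all branch lengths by bounded L-BFGS-B on log parameters from a small set
of fixed starting points; base frequencies are empirical (+F). The
optimizer is deterministic, and a degenerate alignment (one distinct
sequence) returns zero branch lengths with a warning.

## Synonymous substitutions in context

For every branch of the focal clade, a substitution is counted as
observed when parent and child codons differ at exactly one position and
the change is synonymous against the parent codon; an opportunity is any
(site, target base) pair that would be synonymous in that sense, counted
on the branch's parent sequence whether or not the change occurred.
Counting (site, target) pairs rather than sites is the only reading under
which "substitutions that could happen" is well defined at sites with
several synonymous targets. Contexts are the parent-strand 5' and 3'
neighbors; codons with multi-position changes are excluded from both
counts and reported, since a one-step synonymy evaluation is undefined
for them. A strand-merged view adds each class to its reverse complement
(C→T and G→A are one mutational event seen from two strands). Frequencies
are observed/opportunities after summing over branches.

## Amino-acid bias and OU regime tests

Per-taxon amino-acid profiles are codon translations under the standard
code (plastid genes use it), excluding gaps, ambiguity and stops. The
AT-tendency statistic is the Spearman correlation (average-rank ties)
between the 20 amino-acid frequencies and the mean AT content of each
amino acid's codons.

Shifts between heterotrophic and photosynthetic lineages are tested by
fitting an Ornstein--Uhlenbeck process on the tree: a single optimum
(OU1) against two regime-specific optima (OUM), with selection strength
$\alpha$ and diffusion variance $\sigma^2$ shared across regimes. Design
choices where the published configuration is silent:

* the branch carrying the regime shift belongs to the derived regime, so
  the optimum changes at that branch's origin;
* the root state is fixed at the ancestral regime's optimum (one fewer
  parameter); with this convention the tip covariance
  $\sigma^2 e^{-\alpha(d_i+d_j-2m_{ij})}(1-e^{-2\alpha m_{ij}})/(2\alpha)$
  tends to the Brownian covariance as $\alpha \to 0$, which the tests
  verify numerically;
* $\sigma^2$ is shared between regimes (the shift is in the "center
  parameter" only);
* non-ultrametric trees are accepted as-is, covariances coming from
  actual path lengths.

Optima and $\sigma^2$ are profiled out analytically (GLS), leaving a
one-dimensional search over $\log\alpha$ on a fixed 41-point grid with
local refinement -- deterministic, and it guarantees the OUM likelihood
never falls below OU1's (the OU1 design is nested in OUM's for every
$\alpha$). The likelihood-ratio statistic is referred to $\chi^2_1$
(OUM adds one optimum); across the 20 amino-acid tests q-values come from
Benjamini--Hochberg. Calibration under the null (64-tip tree,
$\alpha = 2$, $\sigma^2 = 0.5$) holds the nominal 5% size within
Monte-Carlo error in the test suite (500 replicates).

## Branch-model dN/dS

Codon substitution rates follow the GY94 form
$q_{ij} = \pi_j \kappa^{\mathrm{ts}} \omega^{\mathrm{nonsyn}}$ over the
61 sense codons, with F3x4 frequencies estimated from the data,
$\kappa$ shared, and one $\omega$ per branch class; each class matrix is
rescaled to one expected substitution per codon site. Gamma rate
variation across codon sites is deliberately not modelled. Two contrasts
mirror the published setup: a three-ratio model (heterotrophic clade /
photosynthetic clades / the transition branch on which photosynthesis
was lost) against a null in which heterotrophic and photosynthetic
classes share one $\omega$ while the transition branch stays free
(df = 1); and a two-ratio model isolating the transition branch. The
transition branch gets its own class throughout because it can be
attributed to neither regime. Bounds are $\omega \in [10^{-4}, 10]$,
$\kappa \in [0.1, 50]$; starts are $\omega = 0.5$, $\kappa = 2$; all
branch lengths are optimized jointly, with one deterministic warm
restart. Gap, ambiguous and stop codons are treated as missing data.

## Gene matrix, structure and parsimony

`detect_ir` finds the inverted repeat by seed-and-extend: exact 25-mers
shared between the sequence and its reverse complement, extended
outwards under a mismatch budget (default rate 0.01, minimum length
1000 bp). The published analyses located IR borders by manual searching;
an automated equivalent has to fix these knobs, and they are exposed as
arguments. The longer single-copy region is labelled LSC. For the
synthetic exactness checks the toy-genome generator places boundary
guards (a base never equals its own complement) so the constructed IR is
exactly maximal, and detection runs with a zero mismatch budget -- toy IR
copies are exact, so that is the appropriate setting there.

CDS classification: intact requires an ATG start (ACG is accepted for
genes on the RNA-editing whitelist, e.g. *rpl2*, where editing restores
AUG), a terminal stop, and no internal stop; otherwise pseudogene; no
annotated feature means absent. rRNA/tRNA intactness uses a length
threshold of 70% of a reference length -- a convention of this package,
flagged in output, since no numeric rule is published. Synteny-based
absence inference upgrades "unsampled" to "absent" only when both
flanking genes of the shared collinear order are observed contiguously on
one contig with the gene missing between them.

Gene-loss histories are mapped by parsimony with pseudogene and absent
both coded "lost" (pseudogenization is loss of the functional gene) and
unsampled as missing data. Binary Fitch is the default; Dollo (losses
only) is offered because plastid gene loss is effectively irreversible.
One subtlety matters: among equally parsimonious Fitch reconstructions
there are often some that replace two losses by one loss plus one regain,
or even root the character in the lost state and explain the data with
regains only. Counting "independent losses" by minimizing losses over
*all* MPRs would therefore report absurdly low counts. The package
instead prefers, among MPRs, those with the fewest regains -- the
irreversibility argument made explicit -- and reports the minimum loss
count within that class. The exhaustive enumeration oracle in the test
suite applies the same preference and agrees on hundreds of random
characters; on the worked example this yields three independent losses
of *rps2* and two of *rps18*.

## Synthetic data: what it does and does not emulate

The simulators generate nucleotide alignments under GTR+Gamma (with an
optional non-stationary root composition, so an equilibrium-AT analysis
has something to forecast), codon alignments under the exact GY94
branch-class model the likelihood uses, OU traits by exact Gaussian
transitions, irreversible gene loss, and toy quadripartite genomes. All
are seed-deterministic and return their generating truth. They do not
simulate indel length distributions, genome rearrangements, alignment
error, or context-dependent mutation -- so passing tests demonstrate
correctness of the estimators under their own model assumptions, not
robustness to misalignment or annotation error, which the published
analyses flag as the dominant practical risk for dN/dS in AT-rich,
indel-rich genes.

A note on the published test table: three of the eleven printed p-values
are "0.00" and carry no recoverable precision. The Benjamini--Hochberg
worked example re-derives all recoverable q-values exactly; the three
unrecoverable entries are represented by documented stand-in p-values
chosen only to preserve the published rank order, which provably leaves
every recoverable q-value unchanged. One printed q (0.30) differs from
the value recomputed from its printed p (0.293) by input rounding; the
test allows for that at the printed precision. The published q for the
table's smallest p-value equals the per-rank product $p\,m/\mathrm{rank}$
rather than the step-up minimum $\min_{j\ge i} p_{(j)} m/j$ (the two
differ only for that row); `benjamini_hochberg()` implements the proper
step-up procedure, and the worked example reports both quantities.

## Problem sizes used by the checks

The test suite and the acceptance script use: 4-taxon/8-site exhaustive
likelihood oracles; 8-taxon trees with 3--20 kb alignments for
equilibrium-AT recovery and bootstrap coverage (30 simulations x 150
replicates); 500-codon, 8-taxon simulations for omega-class recovery;
500 null replicates on a 64-tip tree for OU test size; and 100 random
toy plastomes for IR detection. These sizes were chosen so each check is
statistically decisive for the property it tests while the whole suite
stays comfortably desk-scale.
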
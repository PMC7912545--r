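---
title: "Pedigree-based diversity, structure and breed discrimination: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based diversity, structure and breed discrimination: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`peddiv` analyses genealogical (studbook) data: every quantity it reports
is a function of the parent links, never of molecular markers. This
vignette documents the models and conventions behind each stage, the
tunable parameters, what the synthetic-pedigree generator does and does
not emulate, and the numerical choices a user auditing results will want
to know.

## The pedigree substrate

A pedigree is a validated, topologically ordered table of animal records.
Unknown parents are coded `NA` internally; `""`, `"0"`, `"NA"` and
`"UNKNOWN"` are accepted on input. Parent links referencing absent records
create *phantom founders* by default (with a warning), because real
studbooks contain dangling references; this can be escalated to an error.
Birth dates may be ISO dates or bare years; a bare year is anchored at
July 1 so that interval arithmetic in decimal years (365.25-day years) is
unbiased to about half a year. Ids are opaque strings. Cycles through
parent links and duplicate ids are hard errors; an animal recorded as a
sire must not be sexed female (and vice versa).

`subset_population()` implements the two standard reference sets: the
*historical* population (all records) and the *current* population (living
animals). Current subsets retain dead ancestors as computational context;
the statistics' reference set (the `focal_ids` attribute) contains only
the living animals. All downstream `reference` arguments default to it.

## Relatedness machinery

Inbreeding uses the Meuwissen–Luo traversal: for animal *i* only the
vector of path coefficients over *i*'s own ancestors is held, with
Mendelian-sampling variances
$D_j = 0.5 - 0.25(F_{s(j)} + F_{d(j)})$ (unknown-parent terms following
the $F = -1$ convention, so founders have $D = 1$). Animals sharing a
(sire, dam) pair reuse the computed value. The test suite checks the
result against a dense tabular relationship matrix to $10^{-12}$.

Everything else that looks like it needs the full relationship matrix
$A$ goes through the indirect product
$Ax = T\,D\,T'x$ (two linear sweeps over the ordered pedigree per
right-hand side): average relatedness is $A\mathbf{1}/n$, exact mean
coancestries are $x'Ax/2$ for uniform weight vectors, and subpopulation
coancestry means use one product per subpopulation. No dense matrix is
ever formed in the package itself; dense constructions appear only in
test oracles and in the inbreeding partition below.

Conventions worth knowing:

- **Mean coancestry includes self-pairs by default** ($f_{xx} = (1+F_x)/2$).
  This is the convention under which $f_g = 1/(2\bar C)$ recovers $n$ for
  $n$ unrelated founders. For *mating-system* questions the self term is a
  nuisance — self-pairs are not matings and add an $O(1/n)$ upward bias to
  $\bar C$ — so `mean_coancestry(..., include_self = FALSE)` gives the
  distinct-pair mean; the package's random-mating recovery checks use it
  for $\alpha$, while `diversity_summary()` reports the self-inclusive
  $\bar C$ alongside the by-construction
  $\alpha = 1 - (1-\bar F)/(1-\bar C)$.
- **$\Delta F$ for shallow pedigrees**: the rate
  $\Delta F = 1-(1-F)^{1/(t-1)}$ is undefined at $t \le 1$; with only one
  observed generation the rate is taken to be $F$ itself.
- **$\Delta \bar C$** averages pairwise rates over distinct reference
  pairs: all pairs up to 2,000 reference animals, beyond that a seeded
  random sample of 2,000,000 pairs (the choice is reported by the
  arguments, and both routes are exact in expectation).
- **GCI** is the reciprocal sum of squared founder contributions to an
  individual, with contributions halved up the pedigree; unknown-parent
  slots contribute to no founder, and an animal with no known ancestors is
  its own sole founder (GCI = 1). No renormalization of partial
  contributions is applied, so shallow pedigrees yield small GCI.

## Probabilities of gene origin

Founder accounting uses the half-founder convention: the *actual base*
counts an animal with exactly one unknown parent as 0.5. A founder's
probability of gene origin $q_k$ is its mean genetic contribution to the
reference; $f_e = 1/\sum q_k^2$.

Ancestor selection is iterative: at each round the candidate with the
largest *marginal* contribution is chosen, where marginal means the
probability that a reference gene's ancestral path passes through the
candidate while avoiding every previously selected ancestor — implemented
as a blocked upward sweep times the fraction of the candidate's genome not
already explained by the selected set. The origin walk for a reference
gene starts one meiosis up: a reference animal's own genes attribute to
its parents, and an unknown-parent slot leaves its share on the animal
itself (it is its own base individual for the untraced part). Ties are
broken in lexicographic id order, because selection order can move $f_a$
in the third decimal. Selection stops when the residual marginal falls
below `tol` (default $10^{-8}$). A recursive path-enumeration oracle in
the test suite reproduces the greedy sequence exactly on small pedigrees.

One edge is worth flagging: on references that mix founders with their
own living descendants, the marginal partition can come out slightly
*more even* than the founder partition, so $f_a$ can marginally exceed
$f_e$. On the standard reference sets (descendant cohorts) the familiar
ordering $f_g \le f_a \le f_e$ holds, and the test suite asserts it there.

$f_g$ is computed analytically as $1/(2\bar C)$ over the reference
(self-pairs included) or by gene dropping: two distinct allele labels per
founder, one unique label per unknown-parent slot, transmitted
independently down the ordered pedigree; $f_g$ is the reciprocal of twice
the mean simulated identity probability, with a Monte-Carlo standard
error from the replicate spread. Fewer than 100 replicates is refused as
unstable; the tests use 10,000 and check agreement with the analytic
value within three standard errors.

The inbreeding partition uses the exact decomposition
$F_i = \tfrac12 \sum_j T_{s(i)j} D_j T_{d(i)j}$ over common ancestors
$j$; it builds dense gene-flow rows and is therefore restricted to
pedigrees of a few thousand records — adequate for its diagnostic purpose
(naming the ancestors behind inbreeding loops).

## Structure

Realized effective sizes are $Ne = 1/(2\bar\Delta)$ on either rate;
$S = NeC/NeF$ reads $>1$ as subdivision, $<1$ as admixture. Wright's
indices use coancestry-based definitions: with mean self-inbreeding
$\bar F$, within-subpopulation mean coancestry $\bar f_w$ and
metapopulation mean $\bar f_T$ (subpopulations weighted by census size,
a choice the data cannot arbitrate and which is therefore fixed and
documented), $F_{IS} = (\bar F - \bar f_w)/(1 - \bar f_w)$ etc., so
$(1 - F_{IT}) = (1 - F_{IS})(1 - F_{ST})$ holds identically. Nei minimum
distances are the coancestry analogue
$D_{ij} = (\bar f_{ii} + \bar f_{jj})/2 - \bar f_{ij}$. UPGMA
agglomeration is delegated to `stats::hclust(method = "average")` and the
tree serialized via `ape`; ultrametric inputs round-trip exactly.

## Canonical discriminant analysis

The feature table carries, per reference animal: F (%), AR (%), GCI, the
individual non-random-mating term
$\alpha_i = 1 - (1 - F_i)/(1 - \bar C_{breed})$, maximum / complete /
equivalent generations, and offspring number, with breed as the grouping
factor. F and equivalent generations are included deliberately — they are
near-functions of the other columns, and the VIF screen (threshold 4,
iterative, worst first; perfect collinearity is removed first with
infinite VIF) is expected to drop them. The PCA screen
(components with eigenvalue ≥ 1, loading threshold 0.5) is report-only by
default, since low-loading variables may still discriminate.

Forward stepwise selection minimizes the overall Wilks' $\Lambda$
(determinant ratio) and admits a variable when its partial
$F = (\Lambda_{old}/\Lambda_{new} - 1)(n - g - p)/(g - 1)$ reaches
`f_to_enter` (default 3.84, the $\chi^2_1$-derived convention).

The canonical solution whitens the within scatter through its Cholesky
factor and eigen-decomposes the resulting symmetric matrix — numerically
preferable to `solve(W) %*% B` — then scales axes to unit pooled
within-group score variance. Identities maintained to machine precision
and asserted in the tests: $R_c^2 = \lambda/(1+\lambda)$,
$\Lambda = \prod (1+\lambda_m)^{-1}$, Pillai $V = \sum R_c^2$, and the
equality of between-centroid Mahalanobis $D^2$ with squared canonical
centroid distances. Significance uses Bartlett's
$\chi^2 = -(n - 1 - (p+g)/2)\ln\Lambda$ per residual root set and the
standard F approximation for Pillai's trace. Dimensions with
$R_c \ge 0.30$ are flagged meaningful.

Classification is linear (pooled covariance) with priors from group sizes
by default — appropriate for grossly unequal studbook censuses — or
equal. Leave-one-out cross-validation removes each case by the exact
mean/scatter downdating identities (fold priors recomputed from the
training fold), which the tests verify equals a literal refit;
resubstitution predictions are cross-checked against `MASS::lda`. Press'
Q = $(N - nK)^2/(N(K-1))$ on the cross-validated assignments is compared
with $\chi^2_1(0.01) = 6.63$. Unstandardized coefficients are not
reported: they are scale-dependent and add nothing over the standardized
coefficients and loadings.

## The synthetic generator

`simulate_purebred()` emulates a closed studbook: founder generation with
unknown parents, constant census (default 40), right-skewed sire usage
(default: a dominant sire covering 25% of matings, a pattern typical of
popular-sire breeding), near-even sex ratio, 2% unrecorded parent slots,
35% mortality for non-terminal generations (terminal animals alive, so
current subsets are never empty), an 8-year generation gap with ±1-year
jitter so generations overlap. `simulate_composite()` layers a staged
crossing scheme over two purebreds; blood fractions (share of ancestry
from the first breed) are simulator truth labels written to the output
for testing and are never read by the analysis functions. The default
five-stage scheme forms first crosses (1/2), backcrosses to each purebred
(3/4, 1/4), a 3/4 × 1/4 stage that re-fixes the 50:50 genotype, and an
intra-composite stage; `composite_scheme_7030()` instead backcrosses
towards breed A so the terminal composite carries roughly 70% A ancestry.
The real five-stage breeding programme this approximates is known only
qualitatively, so the scheme is a deliberate approximation.

`ideal_population()` is the recovery oracle: discrete generations,
constant even census, equal sex ratio, uniformly random parents, no
mortality. Under it the realized $NeF$ should sit near the census and
$\alpha$ near zero; the acceptance checks run 20 seeds of
$n = 50, g = 10$ and require the seed-averaged $NeF$ in [35, 70] and
$|\bar\alpha| < 0.02$ (computed on distinct-pair coancestry, for the
reason above).

What the generator does **not** emulate: selection on phenotypes, fertility
and seasonality structure, import/export of breeding stock, non-random
missingness (real pedigree gaps concentrate in early decades), and
marker data of any kind. Passing tests therefore demonstrate the
correctness of the algorithms under known genealogical structure — not
that any real studbook satisfies these assumptions.

## Problem sizes and costs

All algorithms are linear or near-linear per pedigree sweep except the
inbreeding traversal (linear in each animal's ancestor count) and the
dense inbreeding partition (capped at 5,000 records). The shipped test
and acceptance workloads use pedigrees of 200–700 animals, 20-seed
replicate bands for stochastic properties, and 10,000 gene-dropping
replicates; these sizes give stable sampling bands for the properties
asserted while keeping a full run in well under a minute on one core.
Larger studbooks (10^5–10^6 records) are within reach of every stage
except `partition_inbreeding()`, whose dense gene-flow rows would need a
sparse implementation.

## Known limitations

- The inbreeding partition and the exact all-pairs $\Delta\bar C$ switch
  to restricted or sampled computation on large pedigrees, as described.
- $f_a$'s tie-breaking (lexicographic) is a convention; other orders can
  shift $f_a$ slightly when marginals tie.
- Wright's indices depend on the census-weighting convention for the
  metapopulation mean; equal weighting would give different
  $F_{ST}$ on unbalanced censuses.
- The CDA assumes a common within-group covariance (linear rule). No
  regularized or quadratic variant is provided.
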
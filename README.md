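# peddiv

Pedigree-based genetic diversity, population structure and breed
discrimination for studbook populations — with composite (multi-breed)
formation in mind.

`peddiv` is aimed at animal-breeding and conservation geneticists who work
from genealogical records rather than markers. Given a studbook (one record
per animal: id, sire, dam, sex, birth date, breed, alive flag) it computes
the standard pedigree-diversity toolkit and a canonical discriminant
analysis that asks how well per-individual diversity parameters separate
the breeds of a composite system:

- **Demography** — pedigree completeness index (PCI), maximum / complete /
  equivalent generations (t = Σ over known ancestors of (1/2)^g),
  generation intervals and parental ages over the four gametic pathways,
  progeny statistics.
- **Relatedness** — inbreeding *F* by the Meuwissen–Luo L-and-D traversal;
  coancestry *f* (f<sub>xy</sub> = a<sub>xy</sub>/2); average relatedness
  AR (row means of the relationship matrix, computed indirectly by the
  Colleau decomposition A = T D T′, never densely); individual rates
  ΔF = 1 − (1 − F)<sup>1/(t−1)</sup> and
  ΔC = 1 − (1 − f)<sup>2/(t_a + t_b)</sup>; non-random mating degree α from
  (1 − F) = (1 − C)(1 − α); the genetic conservation index
  GCI = 1/Σ p<sub>k</sub>² over founder contributions.
- **Gene origin** — founder accounting with the half-founder convention,
  effective numbers of founders f<sub>e</sub> = 1/Σ q<sub>k</sub>²,
  ancestors f<sub>a</sub> (iterative marginal-contribution selection),
  founder genomes f<sub>g</sub> = 1/(2 C̄) (analytic or by gene dropping),
  diversity retained GD = 1 − 1/(2 f<sub>g</sub>), GD\* = 1 − 1/(2 f<sub>e</sub>),
  effective non-founders N<sub>ef</sub> = 1/(1/f<sub>g</sub> − 1/f<sub>e</sub>),
  and the partition of mean inbreeding over common ancestors.
- **Structure** — realized effective sizes Ne = 1/(2 Δ̄), equivalent
  subpopulations S = NeC/NeF, Wright's F<sub>IS</sub>/F<sub>ST</sub>/F<sub>IT</sub>
  from pedigree coancestries, Nei minimum distances
  D<sub>ij</sub> = (f̄<sub>ii</sub> + f̄<sub>jj</sub>)/2 − f̄<sub>ij</sub>, and a UPGMA
  tree written as Newick.
- **CDA** — VIF and PCA screens, forward stepwise selection by Wilks' Λ,
  canonical functions (eigenvalues λ, R<sub>c</sub> = √(λ/(1+λ)), Wilks' Λ
  with Bartlett's χ², Pillai's trace, standardized coefficients, loadings,
  centroids), Mahalanobis D² between centroids, linear classification with
  exact leave-one-out cross-validation and Press' Q = (N − nK)²/(N(K−1)).
- **Synthetic pedigrees** — a seeded generator for closed purebreds, a
  staged two-breed composite (25–75% blood-fraction crossing schemes), and
  a Wright–Fisher-like ideal population, so the whole pipeline runs and is
  testable without restricted studbook data.

## Worked example

Simulate a two-breed composite system (breeds `A`, `B` and a staged
composite `COMP`), restrict to the living population, and run every stage:

```r
library(peddiv)
res <- run_pipeline(run_config(seed = 7))

res$diversity$population[c("mean_F", "mean_coancestry", "alpha")]
#> mean F = 0.0353   mean C = 0.0281   alpha = 0.0074

res$gene_origin[c("fe", "fa", "fg", "GD", "Nef")]
#> fe = 46.65  fa = 41.42  fg = 17.81  GD = 0.972  Nef = 28.81

res$structure[c("NeF", "NeC", "S", "FST")]
#> NeF = 53.07  NeC = 83.48  S = 1.57  FST = 0.0213

round(res$structure$nei_matrix, 4)
#>           A      B   COMP
#> A    0.0000 0.0421 0.0233
#> B    0.0421 0.0000 0.0256
#> COMP 0.0233 0.0256 0.0000

res$cda$model
#> Canonical discriminant analysis: 3 variables, 3 groups, 526 observations
#>     eigenvalue canonical_correlation pct_variance meaningful
#> CF1 2.00720442             0.8169855    95.483719       TRUE
#> CF2 0.09493868             0.2944603     4.516281      FALSE
#> Wilks' lambda (all functions): 0.3037017  Pillai's trace: 0.7541721
```

Reading the output: the living population has retained 97.2% of founder
genetic diversity (GD, from f_g = 17.81); mean inbreeding (3.5%) slightly
exceeds mean coancestry (2.8%), so mating is mildly assortative
(α = 0.007). The coancestry-based effective size exceeds the
inbreeding-based one (S = NeC/NeF = 1.57 > 1), flagging subdivision —
as expected, since the metapopulation holds two closed purebreds plus
their composite. The Nei matrix places the composite between its two
ancestor breeds, and the first canonical function (R_c = 0.82) separates
the breeds on the per-individual diversity parameters with a
leave-one-out hit ratio of 0.711 (Press' Q = 337.7, far above the 6.63
χ²(1) critical value, so classification beats chance).

Pedigree files are read with `read_pedigree()` (see
`inst/extdata/synthetic_studbook.csv` for the CSV dialect), and each stage
is available as a standalone function (`diversity_summary()`,
`gene_origin_report()`, `structure_report()`, `fit_cda()`, ...).

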
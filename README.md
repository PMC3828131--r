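# covarcomp

Comparing amino acid covariation between protein sequence alignments.

## What this is for

Correlated amino acid identities at pairs of alignment columns
(covariation) are a hallmark of natural protein families, but they mix
three causes: maintaining the structure, maintaining the function, and
phylogenetic sampling bias. A powerful way to separate them is to compare
the covariation in a natural family with the covariation in sequences
designed computationally for the same backbone — designed sequences see
only the structure, so the shared covarying pairs are the structurally
constrained ones. `covarcomp` packages that analysis for structural
bioinformaticians: given two alignments over one column frame (and
optionally a structure), it quantifies covariation, tests the overlap of
the two covarying-pair sets, compares amino acid pair propensities,
classifies the physical mechanism behind each covarying pair, and places
pairs in structural context.

## The statistic at its core

For gap-free columns, per-column Shannon entropy
`H_i = -Σ_x P_x log2 P_x` and joint entropy give the mutual information
`MI_ij = H_i + H_j − H_ij`. The background from column entropy and shared
ancestry is removed by the average-product correction,

    MIp_ij = MI_ij − (mean_i · mean_j) / mean,

and `MIp` is z-scored within both columns, the z-scores multiplied, and
the signed square root taken: `Zpx_ij = sign(z_i z_j) · sqrt(|z_i z_j|)`.
Pairs with `Zpx` at least two standard deviations above the mean are the
*highly covarying* set. Two sets A and B are compared by their percent
overlap `100 · 2C/(A+B)` (C shared pairs) with hypergeometric upper-tail
significance over the universe of column pairs ungapped in both
alignments. Transitions between residue pairs at covarying positions are
scored by `PT = φ(x,y) + φ(a,b) − φ(x,b) − φ(a,y)` (φ = 2×2 contingency
correlation) and classified, in fixed priority order, as charge,
cation-pi, pi-pi, size (≥ 18 Å³ compensating volume change), hydrogen
bonding, or residual hydropathy classes.

A synthetic-data module generates alignments with planted two-state
couplings (charge swap RE/DR, size compensation IA/VV, hydrogen bonding
AP/SS, or custom states) and toy structures with planted contacts, so the
entire pipeline runs and is testable offline.

## Worked example

```r
library(covarcomp)

planted <- list(planted_pair(3, 16, "charge_swap"),
                planted_pair(7, 22, "size_comp"),
                planted_pair(11, 27, "hbond"))
spec <- synthetic_spec(n_seq = 300, n_col = 30, planted_pairs = planted,
                       seed = 7)
pair <- generate_alignment_pair(spec, shared_fraction = 1)
model <- generate_structure(30, pair$planted_a, seed = 7)

report <- run_comparison(pair$a, pair$b, structure = model)
report
#> ComparisonReport
#>   natural:  300 seqs, 19 covarying pairs
#>   designed: 300 seqs, 18 covarying pairs
#>   overlap: 27.0% (p = 0.000548)

unlist(report$mechanisms$class_overlap[c("charge", "size", "hbond")])
#>    charge      size     hbond
#> 100.00000  66.66667  66.66667

report$structure$pair_distances$overlap$median_distance
#> [1] 3.139979
```

Reading the numbers: each side detects its three planted pairs plus a
tail of spurious pairs admitted by the 2 SD rule (~2% of the 435 column
pairs), so the overlap percent sits well below 100 even though every
planted pair is shared; the hypergeometric p-value (5.5e-4) shows the
sharing is far beyond chance. The per-class overlaps say both "alignments"
agree on the mechanism of the shared pairs, and the median heavy-atom
distance of shared pairs (3.1 Å) reflects the planted spatial contacts.

The same analysis from a shell:

```sh
Rscript inst/cli/covar.R simulate --n-seq 300 --n-col 30 --pairs 3 \
    --shared 1 --seed 7 --structure --out-prefix toy
Rscript inst/cli/covar.R all --natural toy_natural.fasta \
    --designed toy_designed.fasta --structure toy.pdb --out toy_report
```

which writes `report.json`, `pairs.tsv`, `transitions.tsv`,
`propensity.tsv` and `context.tsv`.

## Package layout

* `R/` — alignment I/O and filtering, covariation (MI/MIp/Zpx),
  set comparison, sequence metrics, pair propensities, mechanism
  classification, structural context, synthetic data, pipeline.
* `inst/cli/covar.R` — thin command-line front end
  (`simulate`, `covary`, `all`).
* `vignettes/covariation-comparison.Rmd` — the methods vignette: model,
  assumptions, parameter choices, limitations.
* `tests/testthat/` — unit, property and acceptance tests with
  independent brute-force oracles.
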
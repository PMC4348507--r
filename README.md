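# pedimpute

Pedigree-based phasing and sequence-variant imputation for founder
populations, built around an indexed dictionary of identity-by-descent
(IBD) cliques.

## The problem

In a founder population, a few whole-genome-sequenced individuals carry —
spread across their chromosomes — most of the haplotypes segregating in
the whole cohort. If the rest of the cohort has dense array ("framework")
genotypes and a known pedigree, sequence variants can be *copied* along
chromosomal segments that are identical by descent, rather than
statistically inferred from population linkage disequilibrium. Calls made
this way follow Mendelian transmission and are accurate across the whole
allele-frequency spectrum, including the rare variants LD-based
imputation handles worst. `pedimpute` is for statistical geneticists
working with such cohorts: deep pedigrees, array genotypes for everyone,
sequence for a small subset.

## The method

1. **Phase** framework genotypes through the pedigree: homozygotes,
   Mendelian trio rules (slot 0 = paternal where the father is typed),
   reconstruction of each parent's haplotypes from transmitted alleles by
   a minimum-recombination Viterbi pass, sibling-template copying, and
   surrogate-relative copying across HMM-detected IBD segments.
2. **Detect IBD** between all C(2n, 2) haplotype pairs with a two-state
   HMM: stationary prior π = kinship φ, transitions
   P(IBD→IBD) = π + (1−π)e^(−λd) over genetic distance d with
   λ = max(1, round(−log₂2φ))/100 per cM, allele-match emissions with
   per-allele error ε. Segments are runs of posterior ≥ 0.5 over ≥ 10
   markers.
3. **Index cliques**: at each marker of interest, haplotype pairs with a
   covering segment form a weighted graph; edges with weight < 0.85 or
   neighborhood (cosine) affinity < 0.9 are pruned and the connected
   components are the IBD cliques — true IBD is transitive, so the true
   graph is a disjoint clique union. The per-marker partitions give O(1)
   "are these haplotypes IBD here?" queries.
4. **Assign parental origin** to quasi-founder haplotypes from the 2×2
   matrix of median kinships between the (possibly ungenotyped) parents
   and each slot's clique members: m = (diag − offdiag)/(diag + offdiag),
   orientation assigned per chromosome when the majority-sign fraction M
   of markers with |m| > 0.25 exceeds 0.75.
5. **Impute** each sequence variant through the cliques at its nearest
   framework marker with a queue: sequenced homozygotes seed the queue,
   cliques are filled by a two-thirds majority vote, and resolved
   heterozygotes enqueue their complementary haplotype. Conflicted
   cliques make no calls.
6. **QC** sequence variants with a generalized Mendelian check: genotype
   discordance between individuals inside their IBD2 segments, pooled by
   variant class, plus per-class call-rate cutoffs.
7. Optionally **merge LD-based calls** (hard calls at probability > 0.99,
   kept per variant only at heterozygote concordance ≥ 0.99 and
   MAF ≥ 1%) into pedigree-missing genotypes, and export paternal /
   maternal haploid panels and a HAPS/SAMPLE reference panel for external
   LD imputation.

A gene-dropping simulator (`simulate_study()`) produces complete studies
with per-marker founder-allele truth and drives all validation.

## Worked example

```r
library(pedimpute)

cfg <- sim_config(n_founder_couples = 8, generations = 3, n_markers = 800,
                  n_chrom = 2, n_seq_variants = 150, n_sequenced = 10,
                  seed = 42)
study <- simulate_study(cfg)
study$framework
#> GenotypeMatrix: 114 samples x 800 markers (2 chromosome(s)), 0.19% missing

qc <- framework_qc(study$framework, study$ped)
table(qc$report$removed_by)
#>    hwe    maf mendel   pass
#>      5     39      1    755

phased <- phase_cohort(study$ped, qc$genotypes)
phased$stats
#>     unphased concordant discordant
#> 1 0.00203711         NA         NA

store <- pairwise_ibd(phased$haplotypes, study$ped)
store
#> IBDSegmentStore: 5360 segments over 228 haplotypes (114 samples)

anchors <- seq(1, nrow(qc$genotypes$map), by = 5)
D <- build_dictionary(store, anchors)
panel <- impute_all(study$variants, D, study$seq_geno, study$sequenced)
panel$rates
#>   phasing_rate allele_call_rate genotype_call_rate
#> 1    0.1006289        0.4396262          0.1806854

gm <- panel_genotypes(panel)
targets <- setdiff(study$samples, study$sequenced)
called <- !is.na(gm[targets, ])
round(100 * mean(gm[targets, ][called] ==
                 study$truth_geno[targets, ][called]), 2)
#> [1] 99.97
```

Reading the numbers: QC removed 45 of 800 simulated markers (mostly the
MAF ≥ 5% restriction); phasing left 0.2% of genotypes unphased; the IBD
scan over all 25,878 haplotype pairs produced 5,360 segments; and of the
genotypes the clique imputation called in the 104 non-sequenced samples
(18.1% — a small 3-generation pedigree leaves many haplotypes with no
sequenced IBD representative, so the clique ceiling, not the algorithm,
limits the call rate), 99.97% match the simulation truth. Accuracy, not
call rate, is the contract of pedigree-based imputation.

A staged command-line front end over the same functions is in
`inst/cli/pedimpute.R`:

```sh
Rscript inst/cli/pedimpute.R all --dir artifacts --seed 1
```

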
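---
title: "Pedigree-based phasing and imputation through IBD cliques: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based phasing and imputation through IBD cliques: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and design

`pedimpute` imputes whole-genome sequence variants, typed in a small
sequenced subset of a founder population, to the rest of a cohort that has
only dense array ("framework") genotypes, using the pedigree rather than
population linkage disequilibrium. The chain of inference is:

1. framework genotype QC;
2. pedigree phasing of framework genotypes into haplotypes;
3. detection of identity-by-descent (IBD) between every pair of haplotypes
   with a two-state hidden Markov model (HMM);
4. indexing of IBD segments into per-marker *cliques* — at any one marker,
   true IBD is an equivalence relation, so the IBD graph is a disjoint
   union of cliques, one per ancestral haplotype;
5. parental-origin assignment of haplotypes, including quasi-founders
   (genotyped individuals without two genotyped parents), via kinship
   separation of their two haplotypes' cliques;
6. queue-based propagation of sequence alleles through the cliques, with a
   two-thirds majority vote;
7. sequence-genotype QC via a generalized Mendelian check: genotype
   discordance across pairs of individuals inside their IBD2 segments;
8. optional merging of LD-based genotype probabilities (e.g. an external
   reference-panel imputation run on the exported HAPS/SAMPLE panel) under
   hard-call, per-variant heterozygote-concordance and MAF filters.

A gene-dropping simulator generates full studies with known truth and is
the basis of every accuracy claim the package's tests make.

# The pairwise IBD HMM

For a pair of haplotypes the hidden state at marker $t$ is IBD or not-IBD.
The stationary prior of the IBD state is the pair's kinship coefficient
$\varphi$ (for the two haplotypes of one individual, the inbreeding
coefficient $F = 2\varphi_{ii} - 1$), clipped to $[10^{-4}, 1-10^{-4}]$.
Kinship is the exact probability that one allele drawn from each
individual is IBD, and the four haplotype pairings of a sample pair
average to it, so it is the natural per-haplotype-pair prior.

Transitions over genetic distance $d$ cM follow the reversible two-state
continuous-time chain with rate $\lambda$:
$$P(\mathrm{IBD}\to\mathrm{IBD}) = \pi + (1-\pi)e^{-\lambda d},\qquad
  P(\mathrm{non}\to\mathrm{IBD}) = \pi(1-e^{-\lambda d}).$$
The default per-pair rate is $\lambda = g/100$ per cM with
$g = \max(1, \mathrm{round}(-\log_2 2\varphi))$ an effective meiosis
count: the expected IBD tract between relatives separated by $g$ meioses
is about $100/g$ cM. $\lambda$ can be overridden per pair.

Emissions depend only on whether the two alleles match. Under IBD a match
has probability $(1-\varepsilon)^2 + \varepsilon^2$ with $\varepsilon$ the
per-allele genotyping error (default 0.005, configurable); under non-IBD
it is $p^2 + q^2$ from the marker's alt allele frequency $p$. Missing
alleles emit 1 in both states. Allele frequencies are estimated from
genotypes where a genotype matrix is available (haplotype-based estimates
collapse to 0/1 at homozygote-only sites in very small cohorts) and are
clipped to $[0.01, 0.99]$.

The forward–backward pass is compiled (Rcpp) and scaled per marker, so
there is no underflow on chromosomes of $10^5$ markers; the same engine
scans all $\binom{2n}{2}$ haplotype pairs (within-individual pairs
included by default, for homozygosity-by-descent in inbred cohorts).
Segments are maximal runs of posterior $\ge 0.5$ of at least 10 markers,
each carrying its mean posterior.

# Phasing

Stages run in a fixed order, and no stage ever contradicts an observed
genotype or unsets a phased allele (the phased set only grows):

1. **Homozygotes** are phased trivially.
2. **Mendelian trio rules**, families in founders-first order: a
   heterozygous child is resolved whenever a genotyped parent is
   homozygous; with a genotyped father, slot 0 is always the paternal
   allele, so non-quasi-founder haplotypes carry parental origin by
   construction. Mendelian-inconsistent sites are left unphased.
   Within the same stage each parent's own haplotypes are reconstructed
   from the alleles they transmitted: a Viterbi pass assigns the
   children's transmitted tracks to the parent's two haplotypes,
   minimizing recombinations (switch cost $\max(3, k-1)$ per track for
   $k$ children, so a single-marker genotype error never forces a spurious
   switch), and the reconstruction resolves sites the per-trio rules
   cannot — notably triple-heterozygous sites.
3. **Sibling template**: remaining sibling sites are phased by copying
   alleles from the most-completely-phased sibling across HMM-detected
   IBD segments.
4. **Surrogate relatives**: any sample with remaining unphased
   heterozygous sites is phased against the phased haplotypes of its
   non-descendant relatives (kinship $\ge 0.05$); an unphased site
   covered by a segment takes the candidate's allele on the covered slot,
   conflicts resolved by the higher segment posterior.

**Known limitation.** A founder couple with exactly two genotyped children
is phase-ambiguous across a crossover: the data cannot tell which child
recombined. Such couples retain occasional switch errors (the simulated
cohort's phase discordance is a few tenths of a percent, concentrated
there). Downstream this shortens IBD segments slightly but does not
corrupt cliques, because a mosaic haplotype is simply IBD with different
relatives on either side of the switch.

# Clique indexing

At a marker, nodes are all $2n$ haplotypes and each covering segment
contributes an edge weighted by its mean posterior (maximum if several
cover). Because true IBD is transitive the true graph is a clique union;
the observed graph is a perturbation of one. Rather than NP-hard cluster
editing we prune and take connected components:

* the **affinity** of an edge is the cosine similarity of the two nodes'
  closed-neighborhood weight vectors (weight 1 at the node itself) —
  large when the nodes share many strongly weighted common neighbors;
* edges with weight $< 0.85$ **or** affinity $< 0.9$ are removed
  (affinities are computed once on the full graph, then both filters
  apply simultaneously);
* connected components of the pruned graph are the cliques; isolated
  nodes are singletons.

This is linear in the number of edges. Raising either threshold only
refines the partition. On planted partitions (five 10-haplotype cliques,
5% spurious bridges at weight 0.86) the recovered partition has Rand
index $\ge 0.95$ against the truth.

**Known limitation.** With the 0.9 affinity threshold, a spurious edge
touching a clique of fewer than five members also drags that node's
legitimate edges below threshold (cosine $\sqrt{4/5} \approx 0.894$), so
the perturbed node is split off — a conservative failure (fewer calls,
not wrong calls). Minimum-edit equivalence with exhaustive cluster
editing therefore holds for perturbed blocks of five or more members
(six or more when the perturbation removes an internal edge), which is
how the oracle tests are scoped.

The per-marker partitions are stored column-wise (`CliqueDictionary`),
giving O(1) same-clique queries, and are built only at requested markers
(variant anchors, thinned grids), chromosome by chromosome.

# Parental origin

Non-quasi-founders inherit slot-0-paternal orientation from Mendelian
phasing. For a quasi-founder $C$ with pedigree-recorded (possibly
ungenotyped) parents $A$ and $B$: at each indexed marker the 2×2 matrix
$K[p, h]$ holds the median kinship between parent $p$ and the eligible
members of the clique of $C$'s haplotype slot $h$ — quasi-founders only,
excluding $C$ and $C$'s siblings, to avoid members whose kinship to both
parents is symmetric by construction. The separation measure
$$m = \frac{(K_{A1} + K_{B2}) - (K_{A2} + K_{B1})}
           {(K_{A1} + K_{B2}) + (K_{A2} + K_{B1})} \in [-1, 1]$$
approaches 1 when the diagonal dominates (slot 0 paternal), $-1$ when the
slots should swap, and is defined as 0 when the matrix is empty. Markers
with $|m| > 0.25$ are informative; with $n_+$ and $n_-$ counting their
signs, $M = \max(n_+, n_-)/(n_+ + n_-)$, and orientation is assigned per
chromosome when $M > 0.75$, by majority sign. Swapping a proband's slots
transposes every $K$, negating every $m$, exchanging $n_+$ with $n_-$,
preserving $M$ and flipping the assignment — an exact antisymmetry the
tests assert.

The within-family step (four parental "bins" per sibship, minimum
recombinations, the three bin-to-parent pairings scored by
$\max(F_1, F_2)/(F_1 + F_2)$ and the pairing maximizing the minimum child
separation chosen) uses the same Viterbi machinery as parent
reconstruction, with pairwise sibling IBD as the observations. The child
separation is normalized to $[1/2, 1]$ so that "maximize the minimum
separation" is scale-free.

**Study design note.** The clique-kinship separation is only informative
when a quasi-founder's clique contains non-sibling quasi-founders —
cousins and beyond. That requires at least two ungenotyped generations
above the quasi-founder generation (so their parents have siblings). The
package's PO validation pedigrees therefore use four generations with the
last two genotyped; with a single ungenotyped generation every eligible
clique member is a sibling and $m \equiv 0$, which is the method's stated
exclusion rule at work, not a defect.

# Imputation

Each sequence variant is imputed independently at the clique partition of
its nearest framework marker (by bp, ties to the left; cliques exist only
at framework markers and the nearest one maximizes linkage to the
variant). The queue algorithm: phase homozygous sequenced genotypes and
enqueue both haplotypes (samples in ascending order, for determinism);
pop a haplotype, put the alleles of already-assigned sequenced haplotypes
in its clique to a vote, and if an allele holds at least two thirds of
the votes (ties at exactly 2/3 pass; the fraction is configurable),
assign it to every haplotype of the clique; any heterozygous sequenced
sample with one haplotype newly resolved has the other phased by
complement and enqueued. A clique with no two-thirds majority — or whose
winning allele would contradict an already-assigned haplotype — is marked
conflicted: the alleles it voted in are withdrawn, while alleles that
propagated onward as complements of sequenced heterozygotes are kept
(they are supported by the observed genotype, not by the conflicted
vote). Sequenced genotypes are never overwritten.

Per-variant independence makes results order-invariant and
embarrassingly parallel. The genotype call rate is bounded above by the
allele call rate, which is bounded by the marker's *maximum call rate* —
the fraction of haplotypes in cliques containing a sequenced haplotype.

Cross-validation masks the framework genotypes of all non-sequenced
samples at every 5th framework marker (configurable), re-imputes them
from the sequenced subset's genotypes, and reports overall and
heterozygote concordance (denominator: called by both, heterozygous in at
least one) by MAF bin.

LD merging consumes external per-genotype probability triples: hard-call
only when the maximum probability exceeds 0.99; keep a variant's LD calls
only when its pedigree-vs-LD heterozygote concordance is at least 0.99
and its MAF at least 1%; kept calls fill only pedigree-missing genotypes.
An LD heterozygote fills the genotype but not the phase. The paternal /
maternal haploid export writes each oriented haplotype as a homozygous
pseudo-sample (missing where unphased) for PO-aware external imputation.

# Sequence-variant QC

The generalized Mendelian check: for each variant, every pair of
sequenced individuals whose IBD2 segment (both haplotypes shared) covers
the variant's position must agree; the class discordance rate is total
discordances over total covering pairs, pooled over the class (singleton
× novelty × type). Under independent per-genotype errors at rate $e$ the
expected discordance is $2e(1-e)$ to first order, which the tests verify
within three standard errors at $e \in \{0.001, 0.01, 0.05\}$, using
IBD2 intervals trimmed by 10 markers per side — the high-confidence
interior — because called IBD2 boundaries are uncertain by a few markers.
Call-rate cutoffs per class default to: known (rs) non-singletons 0.9;
novel non-singletons 0.99; known singletons 0.99; novel singleton SNVs
and deletions 0.99; novel singleton insertions 0.9; comparison is strict
(`call_rate > cutoff`), and an optional high-quality flag is honored as a
prerequisite.

Note that a sequenced subset chosen by the greedy kinship rule is
mutually distant (pairwise kinship < 0.1) and so shares essentially no
IBD2; on simulated studies the pipeline's seq-qc stage legitimately
reports missing rates, and the estimator's accuracy is validated over
sibling pairs instead.

# The simulator

`simulate_pedigree()` builds founder couples and marries each later
generation within itself at random, avoiding pairs with kinship
$\ge 1/16$ (no sibs, half-sibs, avuncular pairs or first cousins —
founder-population marriage practice); sibships are $2 +
\mathrm{Poisson}(\bar c - 2)$ with $\bar c = 4$ by default (large
founder-population sibships; at least two children keep parental
reconstruction identifiable). `gene_drop()` draws founder haplotypes in
linkage equilibrium from the configured allele-frequency distributions
(framework alt frequencies uniform with MAF $\ge 5\%$; sequence-variant
frequencies Beta(0.5, 5), skewed rare so singletons arise naturally) and
transmits them with Poisson crossovers at 1 Morgan per 100 cM (Haldane,
no interference; the map function is the only recombination model used).
Founder-allele labels are recorded per haplotype per marker, so true IBD
is label equality — exactly the transitive relation the clique index
assumes. `make_study()` adds per-allele symmetric genotyping errors and
missingness, picks the sequenced subset greedily (maximize mean kinship
to the unsequenced, pairwise kinship < 0.1 — the stated selection design;
when infeasible it returns fewer with a warning), and exposes sequence
genotypes for that subset only.

The default configuration — 18 founder couples × 3 generations (about
200 individuals, all genotyped), 2 chromosomes × 1,000 markers × 100 cM,
500 sequence-only variants, 20 sequenced samples, per-allele error
$10^{-3}$, missingness $2\times10^{-3}$ — is the study condition for the
headline validation: pedigree-imputed genotypes of non-sequenced samples
agree with truth on called genotypes at over 99% (typically 99.8–99.99%
across seeds), at a genotype call rate around 20–27%. The call rate is
far below the published rates of deep real pedigrees: with only three
generations and 40–72 founder haplotype lineages, many target haplotypes
simply have no sequenced IBD representative, and the clique ceiling —
not the algorithm — binds. What these simulations demonstrate is the
accuracy contract (calls that are made are Mendelian-grade) and the
internal consistency of every stage against ground truth; they do not
demonstrate real-data call rates, LD structure, platform-specific error
patterns, or pedigrees with error.

Validation fixtures deviate from the defaults only where a property
demands different geometry: parental-origin checks use 4 generations with
the top 2 ungenotyped (see above); the exponential-segment-length check
uses parent–child haplotype pairs on one long dense chromosome (2,000 cM,
8,000 markers), because single-meiosis crossover spacings are the one
relationship class whose true tract lengths are exactly exponential —
unilineal classes such as "kinship 1/8" mix meiosis counts and are only
approximately exponential, which a Kolmogorov–Smirnov test at $n$ in the
thousands duly detects.

# Numerical and determinism notes

* All randomness is threaded through explicit seeds; no function disturbs
  the caller's RNG state.
* Forward–backward is scaled per marker (linear domain, no underflow);
  posteriors are invariant under relabeling of the pair.
* Genetic distances of 0 between markers are floored at $10^{-9}$ cM;
  a missing genetic map is imputed at 1 cM/Mb with a message.
* Queue order, clique ids (numbered by smallest member), and tie-breaks
  (`which.min`/first-wins) are all canonical, so identical inputs produce
  byte-identical artifacts; the pipeline runner's rerun test asserts it.
* The exact Hardy-Weinberg test is computed from log-factorials with a
  max-shift, stable at any counts; its two-sided definition sums all
  heterozygote counts whose conditional probability does not exceed the
  observed one (with a $1+10^{-12}$ slack against ties).
* Comparisons follow the printed semantics everywhere: QC removes at
  `p < 0.001`, call rate `< 0.95`, Mendelian errors `>= 5`, MAF keeps
  `>= 0.05`; clique pruning removes `< 0.85` / `< 0.9`; PO assigns at
  `M > 0.75`; class cutoffs pass at `call_rate > cutoff`; the majority
  passes at `>= 2/3`.
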
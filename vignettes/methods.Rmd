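---
title: "Methods: mapping a sex-determining SNP on proto-sex chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a sex-determining SNP on proto-sex chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The genetic model

`protosex` assumes an XX–XY system in which the entire difference between
the sex chromosomes is a single biallelic SNP: heterozygotes develop as
males, homozygotes for the major allele as females. Because the derived
allele is never homozygous in the population (mothers are homozygous,
fathers heterozygous, so offspring are one or the other), the female
phenotype behaves as recessive: homozygosity for one allele is *required*
for female development. Every statistical choice in the package follows
from this model.

Coordinates are 1-based offsets from the 5′ end of the named reference
clone, intervals are closed, and interval length is `end − start + 1`.
Genotypes are unordered allele pairs; phase never lives in the genotype
matrix — it appears only in transmitted-haplotype labels (pedigrees) and in
EM haplotype frequencies (populations). Missing genotypes are `./.` in the
TSV dialect; individuals of unknown sex are excluded from every
sex-conditioned computation.

## Pedigree interval refinement

In a family, the father's haplotypes are labelled X-type (transmitted to
nonrecombinant daughters) and Y-type (to nonrecombinant sons). Phase
inference is a two-pass majority vote: a provisional vote over all
offspring orients each marker, offspring with constant provisional labels
are taken as nonrecombinant anchors, and the vote is repeated over anchors
only. Ties and X/Y conflicts make a marker uninformative; isolated
genotyping errors are outvoted. With no nonrecombinant anchor of each sex
the phase is undetermined and the package refuses to guess — notably, two
opposite-sex recombinant sibs are *provably* consistent with a flipped
phase, so no method could label them.

A marker is excluded from the candidate region when any offspring's
transmitted type there contradicts its sex; the SD interval is the maximal
run of never-contradicted markers, reported as the open interval between
the innermost excluding markers (the region is defined by its boundary
markers). Offspring missing or uninformative at a marker contribute no
constraint there; double crossovers between adjacent markers are invisible
by construction — a documented limitation, not an error source, since they
only make the reported interval conservative. The test suite checks the
rule against a brute-force oracle that tries every marker position and
inter-marker gap for consistency with all transmitted haplotypes and
sexes, and verifies on simulations that the interval always contains the
causal position and never widens as recombinants accumulate.

## The exact association test

Markers are filtered on minor allele frequency (> 0.1, strict) and call
rate (> 0.99, strict), computed from non-missing alleles and individuals;
filtered markers are carried with reason codes. For each passing SNP the
2×2 table is females/males × homozygous-major/other — the collapse implied
by the recessive model. The test is the conditional exact (hypergeometric)
test computed in log space. The two-sided rule is the point-probability
method with relative tie tolerance 1e-7: sum the probabilities of all
tables with the observed margins whose point probability does not exceed
the observed table's. This rule is not cosmetic: for the perfectly
associated table `[[58,0],[0,47]]` the opposite tail contributes nothing
(p = 1/C(105,58) ≈ 5.6e-31), while for `[[53,5],[4,42]]` the opposite-tail
tables do contribute, and the one-sided tail alone (≈ 7.7e-19) would not
reproduce the published two-sided value (≈ 9.9e-19).

The major allele is the most frequent across the whole sample, ties broken
lexicographically and flagged. Missing genotypes are excluded per marker
(pairwise deletion), which is what takes the wild panel from 105 to 104
fish at the intronic SNP. Degenerate margins give p = 1 with a flag.

Multiple testing: Bonferroni with m = markers passing filters (threshold
α/m). The source figures quote a −log10 threshold of 3.2, which is not
0.05/13 (= 2.41) for the 13 analysed SNPs nor α/m for any stated m; the
package implements the standard α/m and surfaces the discrepancy here
rather than reverse-engineering an undocumented constant. The permutation
correction is the family-wise max-T/min-P flavour: sex labels are permuted,
the per-permutation minimum two-sided p across markers is recorded, and the
corrected p is `(1 + #{minima ≤ observed}) / (n_perm + 1)` — an add-one
estimator, bounded below by 1/(n_perm+1), deterministic given the seed. It
is labelled family-wise because the underlying reference software's
convention (per-marker vs experiment-wide) is not documented.

## EM haplotype frequencies and LD

Two-locus haplotype frequencies come from EM over the only ambiguous
genotype class, the double heterozygote, initialized at a 50/50 phase
split, iterated to a max frequency change < 1e-10 (cap 1000 iterations).
A single start suffices: for two biallelic loci the likelihood is unimodal
in practice, and the tests guard this with a grid-search oracle over the
one free haplotype frequency plus a monotone-likelihood assertion for
every EM trajectory. Haplotype-level estimation (rather than composite
genotype correlation) matters here because the information travels through
the 40 double-heterozygous males of the wild panel; that is what makes the
reproduced r² = 0.7 between the coding and intronic SNPs come out right.

From frequencies: D = p_AB − p_A·p_B; D′ = |D|/D_max with
D_max = min(p_A·p_b, p_a·p_B) for D > 0 and min(p_A·p_B, p_a·p_b) for
D < 0; r² = D²/(p_A p_a p_B p_b); LOD = log10 of the likelihood ratio
against the D = 0 model with allele frequencies at their MLEs (the
convention behind "LOD ≥ 2" shading in LD plots). D′ is reported as an
absolute value in [0,1]; the signed D is retained. A locus monomorphic in
the pairwise-complete subset yields a flagged null result, not an error.

One subtlety the tests document: when the *phased truth* of a simulation
has D′ = 1 (a gamete class absent), the EM MLE from *unphased* genotypes
can still land in the interior of the simplex for weakly correlated pairs,
because absence of a gamete class is only softly identified through double
heterozygotes. Complete-LD invariants are therefore asserted on the phased
truth, and on fixtures where the EM solution is exactly determined.

## The synthetic world

The generators produce data with the statistical structure the analysis
assumes; their defaults are the study's scale and they are not tuned to
test outcomes.

**Wild population** (`simulate_wild_population`): 58 females + 47 males
sampled from a forward-time population of 200 individuals per discrete
generation (400 founder haplotypes), 200 generations, 30 SNPs on a
17,500 bp region with the causal SNP at offset 7271. Gametes recombine at
1e-5 per bp per meiosis (females), males at half that — the male:female
map-length ratio near the SD locus is not documented anywhere, so 0.5 is
an explicit, user-configurable placeholder. The per-generation rate is
deliberately high for a 17.5 kb region: 200 generations of it stand in for
the very long ancestral history that gives a large wild population its
low background LD, which is the feature being emulated, and it produces a
mean far-pair r² well under 0.2 with appreciable LD only at sub-kb
distances. Founder variation follows an infinite-sites model on a random
genealogy: each neutral marker's derived allele is one clade of a random
binary tree over founder haplotypes (clades sampled proportional to size,
emulating the common-variant ascertainment of a sequencing-based SNP
screen), so founder LD is tree-like and decays only through recombination.
Neutral mutations never land on the Y clade or its complement: the causal
SNP is the *unique* perfectly sex-linked variant by construction, which is
the package's resolution of the tension between "no recombination implies
complete LD with founder-linked markers" and "the screen must single out
the causal SNP". Mutation is off by default (the founder pool supplies all
variation); the clone simulator likewise models substitutions only — the
region's real repeat content (~2% retroelements) is noted but not
modelled.

**Families** (`simulate_family`): paternal gametes follow a Haldane
(no-interference) crossover process — Poisson crossover count from the
male map length, uniform positions on the cM scale — and maternal gametes
the female map; offspring sex is the paternal allele at the causal marker.
The default cross is fully informative (father heterozygous, mother
homozygous for one paternal allele), degradable via
`informative_fraction`. At the study's screening scale (two flanking
markers 1.6 cM apart on the male map, 1445 sibs) the simulator's
recombinant count is binomial with mean ≈ 23, matching the reported
screen.

**Clone pairs and species panels**: an X/Y clone pair of length L and
target identity q differs at exactly ⌊(1−q)·L⌋ distinct positions
(defaults 14 kb at 99.4%, the sequenced clone values); species panels
(defaults 8/8, 8/8 and 6/7 females/males — the main text and the
supplementary legend disagree on the third species' 6F/7M vs 7F/6M, and
both are parameterizable) share one C/G SNP in perfect sex association
plus species-private neutral SNPs.

Every generator is bit-identical under the same seed; sub-streams are
derived deterministically from one master seed.

What a green test does *not* establish: the simulators have no selection,
no demography, no genotyping error, no indels or repeats, discrete
generations and a single small region — so passing tests certify the
statistical machinery and its contracts, not robustness to the full
messiness of real panels.

## Numerical and degenerate-input choices

* Exact-test tails are accumulated in log space via `log-sum-exp`; the
  enumeration oracle in the tests uses plain `choose()` ratios, a genuinely
  independent route.
* EM convergence is on frequencies (1e-10), not log-likelihood, so
  boundary solutions (frequency 0) terminate cleanly; the log-likelihood
  path is retained and asserted non-decreasing.
* Tie-breaks: major allele lexicographic (flagged); X/Y vote ties make a
  marker uninformative rather than guessing.
* Degenerate inputs favour flagged results over errors where a value is
  conventionally defined (degenerate Fisher margins → p = 1, monomorphic
  LD → null result) and errors where no convention exists (identity of
  all-N sequences, phase with no anchors, interval with every marker
  excluded).

## Known limitations

Indel and repeat variation is not called or simulated; chromatogram-level
heterozygote detection is abstracted into genotype calls; cross-species
coordinates must be pre-mapped to a common reference region; only the
standard genetic code is supported; and the permutation correction is
family-wise only. The pipeline's statistics are all single-locus or
two-locus — no haplotype blocks, no multi-allelic LD, no regression-based
association.
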
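---
title: "Methods: KIR gene-content haplotypes, allelic phasing, LD and novel alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KIR gene-content haplotypes, allelic phasing, LD and novel alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirpop)
```

## The problem

The KIR (killer-cell immunoglobulin-like receptor) complex is a ~150 kb
gene cluster on chromosome 19q13.4 whose haplotypes differ not only in
allele sequence but in *which genes they carry*: whole-gene deletions,
duplications and multi-locus insertions are common. Modern typing
pipelines emit, per individual, (i) an integer copy number for each of the
15 loci (13 genes plus the pseudogenes KIR2DP1 and KIR3DP1) and (ii)
unphased allele calls at 5-digit resolution. This package turns those two
tables into population-level results: gene-content haplotype frequencies,
allelic haplotype frequencies, pairwise linkage disequilibrium (LD), and a
catalog of candidate novel alleles.

KIR2DL2/KIR2DL3 segregate as alleles of one locus (written KIR2DL23), as
do KIR3DL1/KIR3DS1 (KIR3DL1S1); KIR2DL5A and KIR2DL5B are positional
paralogs and are kept distinct. Four framework genes -- KIR3DL3 and
KIR3DP1 bounding the centromeric region, KIR2DL4 and KIR3DL2 bounding the
telomeric region -- are present on nearly all haplotypes, and the two
regions recombine quasi-independently, which is why the package analyses
them separately and couples them afterwards.

## Gene-content haplotype decomposition

A diploid copy-number profile is a vector $c \in \mathbb{N}^{15}$. Given a
catalog $H$ of candidate single-chromosome haplotypes with content vectors
$v_h$, the decompositions of an individual are all unordered pairs
$\{a, b\} \subseteq H$ with $v_a + v_b = c$ restricted to the region's
loci. Enumeration is exact (a residual-lookup over the catalog, verified
in tests against a brute-force double loop); an empty set marks the
profile undetermined.

A haplotype's identity is its content vector plus name. Gene *order* is
carried for display only: copy-number data cannot resolve order, so
inference never uses it.

Ambiguity between decompositions is resolved by frequency weighting, an
EM in miniature: haplotype frequencies $f_h$ start uniform; each
individual's candidate pairs are scored $w_{ab} \propto (2 -
\delta_{ab}) f_a f_b$; fractional counts re-estimate $f$; at convergence
an individual is called **resolved** when its best pair holds a posterior
share of at least 0.95 (the `ratio_threshold`), **ambiguous** otherwise,
and **undetermined** when no catalog pair fits. The 0.95 default is this
package's own operating point: it mirrors conservative practice --
reporting an undetermined fraction rather than forcing calls -- and is a
tunable argument. Reported frequency tables use hard counts of resolved
individuals divided by $2n$, and everything unresolved aggregates into an
explicit undetermined fraction, so the table always sums to one.

Two structural subtleties:

* **Cross-region insertions.** The duplication haplotypes `new1`
  (KIR3DP1~KIR2DL4~KIR3DS1 inserted into tA01) and `new2` (a seven-locus
  block inserted into tA01) are telomeric haplotypes that carry a copy of
  the centromeric locus KIR3DP1 (and, for `new2`, KIR2DS3, KIR2DP1 and
  KIR2DL1). The telomeric region is therefore resolved first and the
  resolved pair's centromeric-locus content is subtracted from the
  profile before centromeric decomposition. If the telomeric side is
  unresolved the centromeric profile is left unadjusted and typically
  comes out undetermined -- a conservative failure mode.
* **Full-haplotype phase.** Regional pairs are joined into full
  haplotypes only when the phase is determinable: when either region is
  homozygous, or when a configured gametic coupling (by default cB04 with
  tB03, and cA03 with tB02 -- couplings observed to be obligate) matches.
  Everything else stays unphased rather than guessed.

Novel-structure discovery implements the residual rule: for each
unresolved profile and each *common* haplotype $h$ (frequency $\geq$ 0.01
by default; "common" is deliberately a parameter because no canonical
cut-off exists) with $v_h \leq c$ locus-wise, the residual $c - v_h$ is a
candidate; residuals recurring in at least `min_support = 2` individuals
are returned, named `discovered:<hash>`, flagged as unordered, and can be
appended to the catalog for a second pass. The support threshold of two
individuals prevents single-individual artifacts from entering the
catalog.

## Allelic haplotype frequencies by EM (gene counting)

Unphased multi-locus genotypes are phased statistically with the standard
gene-counting EM. Gene absence enters as the pseudo-allele `ABSENT`
(copy number below two pads the genotype), which is the standard
treatment for a gene family with presence/absence polymorphism: it lets
presence/absence LD and haplotypes over variable gene content fall out of
the same estimator. Individuals with more than two copies of an included
locus are excluded from the EM at that locus set and reported -- diploid
pair enumeration is undefined for three copies.

* E-step: enumerate all haplotype pairs consistent with a genotype
  (identical genotypes are collapsed into classes first) and weight by
  $(2-\delta) f_a f_b$.
* M-step: $f_h = $ expected count of $h$ over $2n$.
* Convergence: relative change in log-likelihood below `tol = 1e-8`
  (scale-free, unlike a parameter-change criterion). The log-likelihood
  trace is retained and asserted non-decreasing in the test suite.
* Initialization: restart 1 uses the product of observed allele
  frequencies (the independence solution); further restarts (default 10)
  multiply it by seeded Gamma(1) noise, a Dirichlet-style perturbation
  that breaks symmetric local maxima. The best final likelihood wins.
* Output floor: haplotypes with estimated frequency below $1/(4n)$ --
  half an expected count -- are pruned from the report as counting noise,
  but kept in the full frequency attribute used for posteriors.

Convergence settings are this package's choices; they are arguments, not
constants.

Phase posteriors for an individual are the normalized pair weights under
the converged table. Chromosome-level structural assignment
(`assign_structural_phase`) maps each phased chromosome to the catalog
haplotype whose presence/absence pattern matches its non-ABSENT loci;
haplotypes with internal duplications are excluded from matching because
an EM-phased chromosome carries at most one allele per locus.

## Linkage disequilibrium

LD between two loci is computed from the EM-estimated two-locus haplotype
frequency matrix (ABSENT included). Because the loci are highly
multi-allelic, statistics are reported per allele pair via the 2x2
collapse (allele versus rest at each locus):
$D = p_{ij} - p_i q_j$, $D' = D / D_{\max}$ with the usual sign-dependent
$D_{\max}$, and $r^2 = D^2 / (p_i(1-p_i)q_j(1-q_j))$. A monomorphic
margin gives $D' = 0$ with a degeneracy flag rather than an error. A
frequency-weighted mean $|D'|$ per locus pair is also available but is a
package-level summary, not a published statistic.

Significance uses a permutation test: the statistic is the converged
two-locus log-likelihood minus the independence log-likelihood (joint
frequencies set to the product of counted allele frequencies), and the
null is built by permuting one locus's genotypes across individuals, the
per-individual allele pair moving as a unit, so Hardy-Weinberg structure
within each locus is preserved. $p = (1 + \#\{T_{perm} \geq T_{obs}\}) /
(n_{perm} + 1)$. Permutation was chosen over an asymptotic
likelihood-ratio chi-square because the multi-allelic haplotype tables
here are sparse; the reference software used for such analyses does not
document its test, so this scheme is a defined substitute, not a claim
about any other program's internals. Resolving $p < 10^{-5}$ requires
$n_{perm} \geq 10^5$; the pipeline default (199) is sized for smoke runs
and the threshold is a flag.

The strong-LD filter keeps allele pairs with $r^2 > 0.2$ and $D' > 0.7$
(strict inequalities) and, when p-values are present, $p \leq p_{max}$.

## Novel-allele classification and annotation

Classification operates on variable-site vectors over a gene's aligned
CDS positions -- the representation a typing pipeline emits upstream of
any wet-lab confirmation. Against a loaded allele database:

* **known** -- exact match to a database allele;
* **novel SNV** -- at least one site carries a state never observed at
  that site in any allele of the gene;
* **recombinant** -- no exact match, but every site state is individually
  known: a new phasing combination of known variable sites.

The three statuses are mutually exclusive and exhaustive by construction
(property-tested against a brute-force scan). "Novel" is always relative
to a database version, so the version string is carried on the database
object and into every classification table. The nearest allele is the
minimum-Hamming-distance entry with name-order tie-breaking. rsIDs are
opaque pass-through labels; no remote lookup is performed.

Annotation maps a CDS position to exon (1-based inclusive intervals on
the spliced CDS), codon ($\lceil pos/3 \rceil$), and mature-protein
position (codon index minus the gene's signal peptide length; positions
inside the signal peptide are tagged rather than numbered). Substitutions
are scored with the embedded published Grantham matrix (range 5-215,
symmetric, zero diagonal); synonymous changes and stop-gain changes carry
no score. Carrier summaries count individuals once per locus regardless
of how many copies are flagged.

## The synthetic cohort generator

Every analysis stage is testable without protected genotype data because
the generator emulates exactly the inputs the pipeline consumes. Its
defaults describe a European-descent study population of 2,130
individuals:

* Full haplotypes are drawn as (centromeric, telomeric) *pairs* -- the
  cA01~tA01 haplotype at frequency 0.58, the obligate cB04~tB03 and
  cA03~tB02 couplings, the insertion haplotypes new1 (0.009) and new2
  (0.0045), the KIR2DS4-lacking tA02, a KIR3DL2-only telomere, and a
  KIR2DL2 duplication variant of cB02. Independence of the two regions is
  just the special case of a product table. Under these defaults every
  haplotype lacking KIR2DL4 also lacks KIR3DL1S1, and every KIR2DL4
  duplication carries KIR3DL1S1 and KIR3DP1 duplications; an exception
  mass can be configured but defaults to zero.
* Allele tables are conditional on the haplotype, one distribution per
  gene (or per copy, so an insertion block can carry its own diagnostic
  alleles). Defaults encode reported restriction patterns:
  KIR2DL4\*00501 on 99.4% of tB01 chromosomes with KIR3DS1\*01301 fixed
  there; KIR3DL2\*00701/\*018 only on tB01; KIR2DL5B\*00801 only on cB04;
  KIR3DL2\*034 only on tB03; and cA01 allele frequencies chosen so the
  most common centromeric allele-haplotype
  (KIR3DL3\*00901~KIR2DL3\*00101~KIR2DL1\*00302) has frequency near 0.10.
  Residual probability mass is spread over invented catalog alleles; the
  within-haplotype composition is configuration, not a claim about any
  real cohort.
* `deterministic_counts` pins exact carrier numbers (for reproducing
  printed counts such as 72 deletion carriers or 38 insertion carriers):
  carriers are the first $k$ individuals after a seeded shuffle, drawn
  from the pair table conditioned on carrying the target, everyone else
  conditioned on not carrying it.
* Novel-variant injection edits the site vector of one gene copy per
  selected carrier, validating that the edit really is a recombinant
  (matches nothing, all states known) or a novel SNV (an unseen state)
  before applying it, and records truth labels.
* One master seed feeds three named RNG streams (haplotype sampling,
  allele sampling, injection), so stages can be re-run in isolation and
  identical configurations give byte-identical output files.

What the generator does *not* emulate -- and therefore what green tests
do and do not show about real data: there is no genotyping error, no read
misalignment, no missing data, and no within-haplotype allelic LD beyond
what haplotype conditioning induces (two alleles on the *same* structural
haplotype are drawn independently given that haplotype). Recovery
results on synthetic cohorts are statements about the estimators under
the stated sampling model, not about robustness to upstream typing error.
The packaged allele database is likewise a small synthetic stand-in: its
coordinates, exon layouts and signal-peptide lengths mimic KIR2DL1 and
KIR3DL1S1 so that published coordinate conventions (e.g. an exon-5 change
at mature position 151) are exercised, but its sequences are generated
and are labelled synthetic in the file names.

## Numerical and design choices

* Frequencies follow the counting convention $f = \text{count} / 2n$;
  haplotype frequencies are reported to 3 decimals, carrier percentages
  to 2, copy-number percentages to 1.
* Tie-breaks are deterministic everywhere (lexicographic on names), so
  equal-score outputs are reproducible.
* EM degenerate classes (zero total weight under a restart) are rescued
  with an epsilon floor rather than aborted.
* Discovered haplotypes are content vectors only; their display order is
  the donor haplotype's order with the residual appended, flagged
  unordered.
* The test suite runs scaled-down problem sizes chosen to exercise the
  asymptotics that matter: oracle comparisons at $n \leq 100$ with a
  0.001 frequency grid, parameter recovery at $n = 2000$ over 20 seeds
  (tolerance 0.02 for frequencies, 0.05 for $D'$/$r^2$), cohort-scale
  counting checks at $n = 2130$, and permutation calibration at
  $n_{perm} = 99$ over 20 seeds.

## Limitations

* Gene order within a haplotype is not inferred; profiles with more than
  two underlying chromosomes (contamination) are out of scope.
* Full-haplotype phase beyond homozygosity and configured couplings is
  not estimated; family data or long-range sequencing would be needed.
* The EM excludes individuals with duplicated loci from allelic phasing
  at those loci; their alleles appear only in structural results.
* Classification consumes whatever site vectors it is given; upstream
  flagging heuristics of read-based pipelines are not reimplemented.
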
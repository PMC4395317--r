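---
title: "Allele-dropout aware variant calling in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-dropout aware variant calling in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpanchor)
```

## The problem

Sequencing a single cell requires whole-genome amplification (WGA), and
WGA routinely fails to amplify one of the two alleles over a region of
the genome -- *allele dropout* (ADO). Reported ADO rates range from 7% to
44% depending on the amplification platform. At a heterozygous somatic
mutation site, dropping the mutant haplotype leaves a pileup that is
indistinguishable from a clean homozygous-reference site: the cell looks
wild-type, and no per-site quality filter can catch it. These are false
*negatives*, and at 30%-ish ADO rates they dominate per-cell genotype
error.

The remedy implemented here exploits linkage. A germline SNP that is
heterozygous in the individual is heterozygous in *every* cell. If such a
SNP lies within one read length (< 90 bp by default) of a target site, the
two sites sit on the same amplicons and share their amplification fate.
Observing **both** SNP alleles in the cell's reads therefore certifies
that both haplotypes amplified locally, and only then may a non-mutant
call at the target be promoted from "undefined" to "confirmed wild-type".
Observing only one SNP allele flags dropout, and the target stays
undefined.

## Genotype model

Calls are made per pileup column over the ten unordered diploid genotypes
$G = \{A_1, A_2\}$, $A_i \in \{A,C,G,T\}$. Each observed base $b$ with
Phred-derived error probability $e = 10^{-Q/10}$ contributes

$$p(b \mid G) = \tfrac12\, p(b \mid A_1) + \tfrac12\, p(b \mid A_2),$$

and the per-allele term is GC-aware: a misread does not land uniformly on
the other three bases but in proportion to their abundance in the target
region. With composition weights $w_G = w_C = \mathrm{gc}/2$ and
$w_A = w_T = (1-\mathrm{gc})/2$,

$$p(b \mid A) = \begin{cases} 1 - e & b = A \\
e \, w_b / (1 - w_A) & b \neq A. \end{cases}$$

At $\mathrm{gc} = 0.5$ this collapses to the familiar $e/3$ model; at a
GC/AT ratio of $2/3$ (i.e. $\mathrm{gc} = 0.4$) a G or C misread of an
A/T allele carries weight $2/7 \cdot e$. The default
$\mathrm{gc} = 0.41$ is the exome-wide average. The four probabilities
over $b$ always sum to one:

```{r}
comp <- base_comp_model(0.41)
sum(sapply(c("A", "C", "G", "T"), base_given_allele,
           allele = "A", e = 0.01, comp = comp))
```

The prior $p(G)$ is built from the same composition weights as
Hardy-Weinberg products: $p(\{A,A\}) = w_A^2$,
$p(\{A_1,A_2\}) = 2 w_{A_1} w_{A_2}$. This is the only GC-dependent,
normalized, reference-free construction consistent with treating base
composition as the sole prior information; it is deliberately
reference-free so the caller has no built-in pull toward the reference
base. The posterior is
$p(G \mid D) \propto p(G) \prod_{b \in \text{pileup}} p(b \mid G)$.

A genotype is *assigned* only under two gates:

* **depth** -- strictly more than `min_depth = 5` qualified reads;
* **dominance** -- the top posterior must exceed
  `ratio_threshold = 1000` times the sum of the other nine.

Anything else is `UNCERTAIN`. Both thresholds are exposed as parameters;
the depth comparisons are strict (`> 5`, and `> 20` for bulks) as a
literal reading of the calling criteria, with `depth_at_least = TRUE`
available to relax the gate to `>=` for users who prefer the inclusive
convention.

The dominance rule has a useful, perhaps surprising consequence: a
*homozygous* call needs roughly 13 clean reads, because every
reference-matching read only doubles the odds against the heterozygotes
(factor $\approx (1-e)/\tfrac12$), whereas a heterozygous call is reached
quickly once a few reads of each allele are seen (each "wrong-allele"
read costs a homozygote a factor of about $e$). This asymmetry is why
`UNCERTAIN` -- not a spurious homozygous call -- is the normal outcome at
marginal depth.

### Numerical choices

Likelihood products are evaluated in log space with max-subtraction
before normalization; twenty reads at $e = 10^{-4}$ already underflow a
naive product. Ties at the posterior argmax (possible only on degenerate
inputs such as an empty prior region) return `UNCERTAIN` -- a tie can
never satisfy the 1000-fold rule anyway. When the nine non-top posteriors
are numerically zero the dominance ratio is $+\infty$ and the call
proceeds. An empty pileup returns the prior unchanged.

## From anchor calls to the ternary matrix

`classify_ado()` maps the anchor SNP's call to a verdict: heterozygous
means `NO_DROPOUT`, homozygous means `DROPOUT`, `UNCERTAIN` means
`UNINFORMATIVE`. `confirm_wildtype()` then codes each (cell, target):

* `1` -- target called heterozygous for the mutant allele;
* `-1` -- target called homozygous-reference **and** at least one anchor
  verdict is `NO_DROPOUT`;
* `0` -- anything else, including the dangerous case where every anchor
  dropped out.

When several anchors disagree, one `NO_DROPOUT` suffices: regional
dropout boundaries can fall between anchors, and evidence that both
alleles amplified at *any* linked anchor is positive evidence about the
shared amplicons. Anchor evidence is genotype-level, not read-level: the
< 90 bp bound guarantees reads *can* span both sites, but inference is
per site, which keeps the method applicable to any pileup input without
requiring read-backed phasing.

The per-cell codes assemble into a ternary cells-by-sites matrix
(`build_matrix()`), with `NA` reserved for (cell, site) pairs from
different datasets' panels. The bundled 97-cell example matrix is the
primary regression surface:

```{r}
m <- example_matrix()
dim(m)
count_codes(m, -1L, grep("^LC-", rownames(m), value = TRUE))
count_codes(m, -1L, grep("^RC-", rownames(m), value = TRUE))
```

## Self-validation

The strategy can measure its own error rate without any external truth:
take pairs of germline SNPs, both heterozygous in the individual's normal
and tumor bulk, less than 90 bp apart. Whenever one member is called
heterozygous in a cell (both haplotypes amplified), the other member must
be heterozygous too; a homozygous call there is exactly the error that
would corrupt a confirmed wild-type. `validate_pair_concordance()` counts
both orientations of every pair in every cell, since either member can
play the conditioning role; this convention makes the denominator
explicit because published counts do not always state it. Per-cell
false-negative rates without the strategy come from
`estimate_fnr()`: among bulk-heterozygous SNPs with more than `min_depth`
reads in a cell, the fraction not recovered as heterozygous. Both the
unweighted per-cell average and the pooled ratio are reported, as the two
poolings answer slightly different questions and summaries in the
literature do not always distinguish them.

## Mutation identification

`call_mutations()` implements the surrounding somatic pipeline on
already-called per-cell VCF records: strict record filters
(QUAL > 20, FS < 40, QD > 1.5, GQ > 20, depth > 5 in cells and > 20 in
bulks), heterozygous support in at least three tumor cells, a
confidently homozygous-reference normal bulk, presence in the tumor
bulk, exclusion of known polymorphisms (site lists plus a
minor-allele-frequency table with a strict 0.01 cutoff), an
amplified-region blacklist, and optional target regions with 90 bp
flanks. An absent annotation fails its filter rather than passing it: a
record that cannot demonstrate quality is not evidence.

The normal-bulk rule deserves emphasis. A germline SNP thinly covered in
the normal can drop an allele there too, pass for homozygous, and turn
every tumor cell's genuine heterozygosity into an apparent recurrent
somatic mutation. The pipeline therefore refuses to evaluate any site
whose normal-bulk genotype is missing, shallower than 20 reads, or not
`0/0` -- and refuses to run at all without a normal bulk. The three-cell
support rule is the fixed default; `min_support_cells()` exposes the
underlying binomial tail computation (smallest $k$ with
$P[\mathrm{Bin}(n, \mathrm{fp}) \ge k] < \alpha$) for users who know
their per-cell false-positive rate, but since that rate is
dataset-specific the literal $k = 3$ is what the pipeline uses unless
told otherwise.

## Clonal-incompatibility detection

Under clonal growth, mutations arising in disjoint lineages never
co-occur in a cell. Over a ternary matrix the telltale pattern for sites
$(a, b)$ is a cell triple: $x = (1, -1)$, $y = (-1, 1)$, $z = (1, 1)$.
Because the $-1$ entries are *confirmed* by linked SNPs, loss of
heterozygosity or dropout in $x$ or $y$ cannot explain the pattern away;
a hit implies recurrent mutation, cell fusion, or an artifact.
`find_incompatible_cases()` enumerates every witness triple exhaustively
and normalizes orientation (each unordered site pair reported once,
`cell_x` carrying `site_a`'s mutation). Site pairs on one chromosome
within 90 bp are flagged as possible shared-amplicon artifacts but not
suppressed -- suppression would be a judgment the data cannot support
either way. On the bundled matrix the enumeration yields two
incompatible site pairs with five witness triples in total.

## What the simulator emulates

`simulate_truth()` / `simulate_reads()` generate the statistical
structure the method assumes, so every claim above is testable against
known truth:

* **regional dropout** -- dropout is sampled per (cell, amplification
  segment), silencing one uniformly chosen haplotype across the whole
  segment. This regional structure is the method's load-bearing
  assumption: linked sites share fate because they share segments.
  `segment_length` (default 10 kb, a typical WGA amplicon scale) is
  deliberately a knob -- shrinking it toward the read length breaks the
  assumption and exposes the failure mode of anchors that straddle a
  segment boundary, which real data never lets one isolate.
* **germline SNPs** -- placed at density 0.004/bp (the observed ~0.4%
  polymorphic fraction of exonic sites), a configurable fraction of them
  as pairs within 90 bp; alleles phased once per individual onto two
  haplotypes.
* **somatic mutations** -- assigned to nodes of a perfect binary lineage
  tree; a cell carries the mutations on its root path. An optional
  fusion event gives designated cells the union of two leaves' mutation
  sets -- the mechanism that generates genuinely incompatible patterns.
* **reads** -- Poisson depth (mean 30 in cells, 50 in bulks), uniform
  haplotype sampling among surviving haplotypes, and misreads with
  probability $e$ landing on the other three bases with the same
  GC-weighted distribution the caller assumes. Phred quality is a point
  mass at `phred_q` (default 30): a degenerate quality distribution
  keeps text round-trips exact and removes a nuisance dimension from
  parameter-recovery tests.
* **the shallow-normal scenario** -- `low_normal_depth_sites` forces
  thin normal-bulk coverage at chosen SNPs to reproduce the
  germline-miscall mechanism end to end.

Defaults were fixed once at field-typical values (ADO 0.2 inside the
reported 7-44% range; GC 0.41; 90 bp reads) and are not tuned per test.

What the simulator does **not** model -- and what passing tests therefore
cannot show about real data: alignment and mapping artifacts, chimeric
WGA reads, strand bias (the FS filter is exercised only via synthetic
records), copy-number variation, non-uniform coverage along the genome,
and quality-score miscalibration. In particular the simulator's error
model matches the caller's by construction; on real data the GC weights
are an approximation.

The test suite and the bundled acceptance script run this machinery at
fixed problem sizes -- 10,000 SNP loci in 4 cells for false-negative-rate
recovery (the Monte-Carlo unit for its standard error being the
(cell, segment) pair, since dropout is regional), and twenty 12-cell
replicates for the clonal logic -- sizes chosen to make the Monte-Carlo
bands a few percent wide.

## Worked example

```{r}
cfg <- sim_config(seed = 7, n_cells = 6, genome_length = 2e5,
                  n_snps = 400, frac_paired = 1, n_somatic = 10,
                  ado_rate = 0.3, depth_mean = 40, lineage_depth = 1)
truth <- simulate_truth(cfg)
reads <- simulate_reads(truth)
comp <- base_comp_model(cfg$gc_content)

calls <- do.call(rbind, lapply(names(reads$cells), function(id)
  cbind(cell = id, call_genotypes(reads$cells[[id]], comp = comp))))

# naive recovery: the dropout rate shows up as a false-negative rate
estimate_fnr(truth$snps, calls)

# anchored confirmation: how many wild-types can be *confirmed*
targets <- truth$muts[, c("chrom", "pos", "ref", "alt")]
pairs <- find_linked_pairs(targets, truth$snps)
codes <- confirm_wildtypes(targets, pairs, calls)
table(codes$code)
```

## Known limitations

The strategy's reach is bounded by SNP density: with ~0.4% of exonic
sites polymorphic, most candidate sites simply have no anchor within one
read length and can never be promoted to confirmed wild-type. Anchors
very near segment boundaries can, in principle, report the neighboring
segment's amplification fate; the simulator quantifies this regime but
the package applies no correction for it. The caller assumes
error-independent reads -- amplification errors that occurred early in
WGA violate this and are not modelled. Indels, multi-allelic sites and
copy-number effects are out of scope throughout.
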
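---
title: "Hologenome profiling with type IIB restriction tags: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hologenome profiling with type IIB restriction tags: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holo2brad)
```

## The problem

Holobiont samples — a host animal together with its symbiotic microbiota —
are dominated by host DNA, often to the point that fewer than 1 % of
sequencing reads are microbial. Shotgun metagenomics is wasteful and
amplicon sequencing is low-resolution in this regime. Reduced-representation
sequencing with a type IIB restriction enzyme offers a way out: the enzyme
excises a uniform-length fragment ("tag") around every occurrence of its
recognition site, so host and microbial genomes alike are represented by a
predictable, enumerable set of fixed-length tags. If a reference database
records which canonical tag sequences are unique to the host and which are
specific to a microbial taxon, a single library supports both host
genotyping and microbial community profiling.

`holo2brad` implements that whole workflow: in silico digestion, hologenome
database construction, read QC and tag extraction, dual-stream
classification, abundance estimation, codominant genotyping, and the
downstream community and population statistics.

## In silico digestion

An `enzyme_spec` describes the tag geometry: an IUPAC recognition pattern
with a fixed number of excised flanking bases on each side. The default,
`bcgi()`, uses the bipartite recognition `CGANNNNNNTGC` with 10-nt flanks,
giving 32-nt tags (`10 + 12 + 10`); the 2-nt terminal overhangs of the
physical fragment are excluded, and the geometry is fully configurable so
other type IIB enzymes can be expressed.

`find_sites()` reports every match of the pattern (plus strand) and of its
reverse complement (minus strand), overlaps included. Degenerate pattern
positions act as wildcards; an `N` in the subject never satisfies a fixed
pattern base. `extract_tags()` excises the window
`[site - left_flank, site + 12 + right_flank)`; windows that run off the
contig or contain a non-ACGT base are skipped and tallied rather than
expanded — degenerate tags would inflate false database matches.
Because sequencing observes tags in unknown orientation, every tag is keyed
by its **canonical form**, the lexicographic minimum of the sequence and its
reverse complement. Coordinates are 0-based, half-open, plus-strand;
soft-masked lowercase is uppercased before matching.

## Hologenome database construction

For each microbial genome the digest is reduced to its **single-copy** tags
(occurrence count exactly 1): multi-copy tags cannot serve as quantitative
taxon markers. A tag that is multi-copy in genome A but single-copy in
genome B is treated as absent from A for specificity purposes.

Each tag's **specificity rank** is the deepest of the seven taxonomic ranks
at which all genomes carrying it share the same label, scanning kingdom to
species and stopping at the first disagreement (a lowest common ancestor
over lineage tuples). Tags that disagree already at kingdom are
*nonspecific*: excluded from the profiling map, counted in statistics.
"Unresolved" placeholder labels are ordinary labels — two genomes share a
rank only if the literal strings match, which is how unresolved lineages
remain individually detectable species.

The host side keeps the host genome's single-copy canonical tags. A final
**cross-deredundancy** pass deletes every canonical tag present on both
sides from *both* sides, so classification is unambiguous; microbial
genomes (and species) left with no species-specific tag are marked removed
and excluded from the theoretical counts. The per-species count of
species-specific tags (the *theoretical tag count*) is the abundance
normalizer below. The database serializes to a sorted, versioned,
gzip-compressed TSV so rebuilds from identical inputs are byte-identical.

Two design points were genuinely open and resolved as follows. The
"two rounds of redundancy removal" for host tags are implemented as
(1) single-copy filtering within the whole host genome and (2) the
host-versus-microbe cross-removal; no per-contig round exists. And
rank-specific fractions are reported both per exact rank and cumulatively
(at-or-deeper), since the latter is what a profiler usable "at rank r"
actually needs.

## Read processing

`quality_filter()` drops a read iff it contains an ambiguous call (`N`), a
homopolymer run strictly longer than 10 nt, or strictly more than 20 % of
bases below phred 10. The homopolymer wording "exceeding 10" is read as
runs of 11+. Every read failing any rule is dropped; the report attributes
each drop to the first matching rule in the order N → homopolymer →
low-quality. `extract_read_tags()` then takes, per read, the leftmost
recognition match on either strand whose full window fits inside the read —
one tag per read, because the physical insert of a type IIB library is a
single tag. Paired-end mates are independent reads for the same reason.

## Classification and abundance

`classify_observations()` routes each observed canonical tag to the host
stream, the microbial stream, or *unassigned*, and reports mapping rates as
fractions of site-bearing tag observations. Species evidence accumulates
only over species-specific tags: for species *i*, `reads_i` (read count) and
`tags_hit_i` (distinct tags observed). Presence is called by the G score

\[ G_i = \sqrt{\mathrm{reads}_i \times \mathrm{tags\_hit}_i} \ge 5 \]

which demands corroboration — 25 reads on a single tag, or 5 reads spread
over 5 tags. The threshold is exposed (`g_threshold`); 5 is the package
default and the value used throughout the examples. Relative abundance
normalizes read counts by the species' theoretical tag count,

\[ c_i = \mathrm{reads}_i / T_i, \qquad p_i = c_i / \textstyle\sum_j c_j , \]

over detected species. Read counts, not distinct tags, carry the
quantitative signal; distinct tags feed only the presence score. Unassigned
tags are excluded from abundance but reported.

## Host genotyping

Host-routed observations — plus unassigned observations, since a SNP allele
differs from its locus reference and cannot exact-match the host set — are
assigned to loci by Hamming distance over both orientations (`max_mismatch
= 2`); exact matches always win, equidistant ties are discarded as
ambiguous. Per locus, the two most frequent alleles with counts
\(n_1 \ge n_2\) contest a binomial likelihood: heterozygous iff

\[ \mathrm{Binom}(n_2;\, n_1+n_2,\, 0.5) > \mathrm{Binom}(n_2;\, n_1+n_2,\, \varepsilon), \]

with sequencing-error rate \(\varepsilon = 0.01\) by default and ties going
to homozygote. Loci with total depth below 4 are *undetermined* — the
high-confidence coverage gate. Alleles beyond the top two count toward
depth (for the gate) but not the contest, which buys robustness to rare
errors. Downstream, the allele-sharing (identity-by-state) distance
`1 − mean(shared copies / 2)` feeds a from-scratch Saitou–Nei
neighbor-joining implementation (deterministic smallest-index tie-breaks,
negative branch lengths clamped to zero), and PCA runs on mean-centred
0/1/2 dosage coding with undetermined calls imputed to the locus mean (a
config switch drops incomplete loci instead). PCA signs follow the
largest-magnitude-loading-positive convention.

## Community statistics

Shannon (natural log by default, switchable to log2), Simpson
\(1 - \sum p_i^2\), and Chao1 in the bias-corrected form
\(S_\mathrm{obs} + F_1(F_1-1) / (2(F_2+1))\) — always bias-corrected, so the
estimator is defined when no doubletons exist (a deliberate divergence from
the classical \(F_1^2/2F_2\)). Bray–Curtis is \(\sum|x-y| / \sum(x+y)\).
PERMANOVA partitions squared distances into within- and between-group sums
with the one-way pseudo-F, and estimates p as
\((1 + \#\{F^* \ge F\}) / (1 + N)\) over seeded label permutations — never
exactly zero, bit-reproducible given the seed. Applying a PERMANOVA to a
univariate alpha-diversity index is supported (Euclidean distance of the
index) but unusual, and the package does not endorse it beyond
compatibility.

## MAG quality control

`filter_mags()` retains a metagenome-assembled genome iff completeness is
strictly above 20 %, contamination strictly below 10 %, and genome size is
within 1–6 Mb inclusive. The size bounds are inclusive because cohorts
contain genomes at exactly 1.00 and 6.00 Mb that pass; the quality bounds
are exclusive per "above"/"below" phrasing. The packaged 57-MAG coral
cohort (`inst/extdata/coral_mag_qc.tsv`) reproduces mean completeness
57.84 ± 26.73 % and contamination 3.14 ± 2.91 % when summarized with
`summarize_mags()`; its recomputed mean genome size (2.43 ± 1.61 Mb) is
reported but not asserted anywhere, since the published rounded column does
not support a tighter statement.

## The synthetic holobiont generator

`sim_config()` defaults encode the study conditions the package is tested
under: 20 microbial species with log-normal (sdlog = 1) relative
abundances, a diploid host, **99 % host read contamination**, 0.5 % per-base
substitution error, and constant phred-38 qualities. Genomes are built from
site-free background (rejection/mutation sampled until no recognition site
remains) with a planted, screened tag at each site, and verified by
digestion — truth tables are exact, not approximate. Host SNPs are placed
strictly inside tag windows, never on a fixed recognition base, so every
locus survives digestion on both haplotypes; both haplotypes share one
spacer backbone. Reads embed the full 32-nt tag at a random offset in a
50-nt read padded with inert A/C-alternating filler that provably cannot
complete a recognition site across the junction; real PE150 reads are
longer, but only the tag is informative and the shorter filler keeps memory
flat. What the generator does *not* emulate: indels, quality decay along
the read, amplification and GC bias, chimeras, and real taxonomic sequence
similarity (planted tags are random, so cross-mapping between species is
absent). Passing recovery tests therefore demonstrates correctness of the
pipeline's bookkeeping and statistics under the stated noise model, not
robustness to every artefact of real libraries.

## Verification sizes and numerical choices

The test and acceptance workloads are sized to make their statistical
claims cheaply decidable: digestion is cross-checked against a naive
both-strand scanner on 100 random genomes of 1–50 kb; specificity against
an exhaustive per-tag LCA on 10-genome toy taxonomies; abundance recovery
and replicate concordance run at 3×10^6 reads with 99 % host fraction
(≈3×10^4 microbial tag reads — about one-seventh of a full-scale lane's
microbial yield, which still leaves the r ≥ 0.99 recovery check comfortably
decidable); genotype recovery uses 200 loci at 20× mean depth over 20
replicate pairs; PERMANOVA is validated against exhaustive enumeration at
n = 6 and a 500-replicate null calibration. Determinism relies on R's
default Mersenne-Twister stream, isolated with an internal seed guard so
library calls never perturb a caller's RNG state. Ties are broken
deterministically everywhere (lexicographic alleles, smallest-index NJ
pairs, plus-strand before minus at equal offset).

## Known limitations

Tag-space Hamming matching replaces genome alignment, so host loci are the
tags themselves and structural context (flanking coordinates, linked sites)
is out of reach. Specificity is only as good as the supplied taxonomy, and
a database built from few genomes per species will overstate
species-specificity. Abundance normalization assumes species' theoretical
tag counts are well estimated from their reference genomes; incomplete
MAGs bias \(T_i\) downward and inflate \(c_i\). Differential-abundance
testing and population-structure admixture modeling are intentionally not
reimplemented; the profiler exports read-count tables for the established
external tools.
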
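---
title: "Methods: polyploid amplicon haplotype analysis in polyhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polyploid amplicon haplotype analysis in polyhap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyhap)
```

## Scope and model

polyhap analyzes clone-sequenced PCR amplicons from autopolyploid genomes.
The motivating design surveys five sucrose synthase gene fragments in three
octoploid *Saccharum* species: an intron-containing ~500 bp region is
amplified from genomic DNA, cloned, and 70–119 colonies are sequenced per
gene per species. Each sequenced clone is one molecule drawn from the eight
homologous chromosomes, contaminated by two artifact processes: per-base
substitution error and PCR template switching, which joins the 5' part of
one template haplotype to the 3' part of another. All inference in the
package is organized around clone support as the defense against these
artifacts.

Because the original clone sequences are not deposited in a public archive,
the package pairs the analysis pipeline with a generative simulator whose
defaults encode the study conditions, so that every stage can be validated
against known truth.

## The simulator

`simulation_config()` fixes the study conditions; `simulate_study()` draws
loci, haplotypes and clone libraries from them.

**Loci.** Each fragment is laid out exon–intron–exon, with the intron
occupying a configurable fraction (default 0.4) of the fragment — the
published design states only that the amplicons contain both exonic and
intronic sequence, and reports that intronic SNPs dominate some fragments,
so the exact boundaries are free parameters here. Exonic bases are drawn as
sense codons honoring a random reading-frame offset, so the reference CDS
always translates without internal stops (a property the protein stage
relies on and the tests verify).

**Species and polymorphism.** The three species follow the fixed topology
`((A, B), C)`: fixed substitutions accumulate at `divergence_rate` per bp
per branch unit, with the C lineage carrying twice the A/B split depth
(branch units 1/1/2). Polymorphic sites are laid down in tiers — shared by
all three species, shared by each pair, and species-private — at per-bp
densities calibrated to the published shared-SNP table: 6/2589 shared by
all three, an extra 9/2589 by the sister pair, 1/2589 and 5/2589 by the
two mixed pairs, and within-species totals of 24, 32 and 36 per 2589 bp.
(The published within-species total for the third species prints 38, but
its own row sums to 36 and the published average of one SNP per 72 bp
matches 36; the simulator is calibrated to the self-consistent value and
the discrepancy is surfaced by `audit_published_tables()`.) Shared sites
are placed only where the carrier species' backgrounds agree, so a shared
SNP has the identical ref/alt pair in every carrier — matching the
"identical SNPs" definition used downstream.

**Haplotypes.** Each species carries 3–8 haplotypes over its 8 chromosomes.
The first haplotype is ancestral: it carries the reference allele at every
polymorphic site, which is what allows consensus (cross-species) haplotypes
to arise whenever no fixed difference separates two species at the scored
coordinates. Derived haplotypes carry each alternate allele in a random
non-empty subset. Multiplicities over the 8 chromosomes are one each plus a
Dirichlet–multinomial allocation of the remainder, with the ancestral
haplotype up-weighted (`ancestral_weight`, default 4): the study system
shows consensus haplotypes at markedly higher frequency than species-
specific ones, and the up-weighting reproduces that enrichment direction
without targeting any particular frequency value.

**Clones.** Each clone copies a uniformly drawn chromosome; with
probability `chimera_rate` (default 0.05) it is recombined once with the
haplotype of another chromosome at a uniform internal breakpoint — the
simplest mechanism consistent with the PCR-recombination concern the design
guards against; multiple switches per molecule are not modeled. Per-base
errors are substitutions only, at `per_base_error_rate` (default 0.001);
indels are out of scope throughout, which keeps the alignment problem
well-posed and matches the substitution-only analysis downstream. All truth
(source haplotype, chimera partner and breakpoint, error positions) is
recorded for validation.

**What the simulator does not emulate.** Real chromatogram quality
gradients, primer-proximal error structure, indel polymorphism, dosage
differences among more than 8 homologs, and locus-specific mutation-rate
heterogeneity. Passing the recovery tests therefore demonstrates
correctness of the inference machinery under the declared error model, not
performance guarantees on arbitrary real libraries.

## Alignment

Clones are anchored to their reference fragment by global
Needleman–Wunsch–Gotoh alignment (Rcpp implementation; match +1, mismatch
−1, and affine gaps where a run of length *g* costs `gap_open + g ×
gap_extend`, defaults −4/−1). The original analysis used interactive tools
without a stated scoring scheme, so the scoring is configuration-exposed,
and a `min_identity` retention threshold (default 0.90) stands in for the
study's manual quality trimming — no quantitative criterion exists in the
source protocol, and the threshold is flagged as this proxy. Alignment
columns are projected onto reference coordinates: clone insertions are
dropped with a warning (substitution-only analysis), deletions become gap
characters that never support an allele. Ambiguity codes other than `N` are
rejected at parse time; `N` scores zero everywhere. The traceback
tie-breaks deterministically (substitution, then gap-in-clone, then
gap-in-reference), and the test suite checks optimality against exhaustive
enumeration of all global alignments for short strings.

## SNP calling and summary statistics

A column yields a SNP when at least two alleles each reach `min_support`
clones; the reference allele counts toward its own threshold, and `N`/gap
characters are ignored. The default of 3 follows the stricter of the two
printed support rules (report level: "at least three sequences"; protocol
level: "at least two colonies", available as `min_support = 2`).
Multi-allelic columns are one site with several alternates and count once
in totals. bp/SNP is computed as total bp over total SNPs, rounded half-up
(107.875 → 108, 80.9 → 81 — the behavior that reproduces the published
rounding; R's default half-to-even would not). Sharing between species
requires the identical position and allele set; union counts deduplicate
SNP identities across species. Published rows whose printed totals
contradict their own cells are flagged by `audit_published_tables()`
rather than reproduced or corrected.

## Haplotypes and consensus classes

Haplotypes are unique allele vectors over the called SNP positions; clones
with `N` or a gap at any SNP position are excluded from haplotyping, and
vectors supported by fewer than `min_haplotype_support` clones (default 2,
independent of the SNP threshold) are discarded and logged. Output order is
descending clone support, then lexicographic allele vector, for stable
reports.

Cross-species equivalence is evaluated on the union SNP coordinate set of
each gene — species call different SNP subsets, and the union set is what
makes "common between at least two species" well-defined. The source
analysis does not state whether its consensus classes were defined on SNP
vectors or full fragment identity; we chose union-coordinate identity and
flag the choice. Each haplotype is represented by its per-column majority
consensus sequence over member clones (alphabetically first base on ties),
restricted to the union coordinates. A class is consensus when ≥ 2 species
contribute; the consensus frequency is the percentage of retained clone
fragments falling in consensus classes. Support enrichment of consensus
haplotypes is tested with a Welch t-test (`stats::t.test`), with the
zero-variance degenerate cases the textbook formula still covers handled
explicitly (equal means → t = 0, p = 1; distinct means with zero standard
error → infinite statistic).

## Proteins

CDS extraction is annotation-driven (exon concatenation, frame-offset trim,
partial-codon trim) rather than six-frame ORF scanning: fragment phase is
known for simulated loci, and homology-based frame inference is outside the
package's scope. Translation uses the standard code; a stop terminates
translation and is rendered `*`; codons containing ambiguity characters
warn with their position and render `X`. Identical amino-acid sequences
within a gene × species collapse into one deduced protein variant, so the
variant count can never exceed the haplotype count. Molecular mass sums
Expasy average residue masses plus one water; the isoelectric point is
found by bisection on the Henderson–Hasselbalch net charge under the EMBOSS
pKa set (N-terminus 8.6, C-terminus 3.6, C 8.5, D 3.9, E 4.1, H 6.5,
K 10.8, R 12.5, Y 10.1), fixed so results are bit-exact across runs. The
published full-length protein descriptors (816–866 aa) refer to
cDNA-derived proteins that cannot be reconstructed from ~500 bp fragments;
only fragment-level proteins are deduced here, so no numeric target is
attached to descriptors. Pairwise protein similarity uses global BLOSUM62
alignment with −11/−1 affine gaps, reporting identical columns over
alignment length.

## dN/dS and phylogenies

`nei_gojobori()` implements classic unweighted NG86: per-codon synonymous
site fractions enumerate the three single-base neighbors per position,
excluding changes through stop codons from numerator and denominator; site
counts are averaged over the two sequences, so N + S = 3 × codons exactly.
Differences in codons with 2–3 changes are averaged with equal weight over
all mutational orderings, excluding stop-crossing pathways (if every
pathway is blocked — possible only in contrived cases — all pathways are
used with the stop treated as an ordinary residue, and this fallback is the
documented behavior). Proportions are Jukes–Cantor corrected,
d = −(3/4)·ln(1 − (4/3)p), with p ≥ 3/4 reported as saturated. The source
methods cite a PAML-based pipeline whose exact settings are unknown; NG86
as specified here is the declared method, not a PAML emulation. Pairs with
saturated or unusually large dS are excluded from the selection summary via
`ks_max` (default 3.0 — the source says only "unusually large", so the
threshold is a config value and exclusions are always flagged). The
remaining pairs partition into Ka ≥ Ks and Ka < Ks.

Codon alignments for rate estimation come from `back_translate()`, which
maps each aligned residue to its source codon and verifies the translation
round-trip. In the pipeline, all fragments of a gene share the locus frame,
so their CDSs are codon-aligned by construction and the cross-species pairs
compared are each species' top-supported haplotype.

Trees are built by neighbor joining (Saitou–Nei, via `ape::nj` behind a
validated surface; negative branch lengths are clamped to zero with a
warning) on p-distances (Poisson-corrected distances available) over
deduced protein sequences. Bootstrap support resamples alignment columns
with replacement, rebuilds the tree per replicate, and reports the
percentage of replicates containing each internal-edge bipartition of the
full-data tree; replicate column indices are retained for audit. Replicates
that leave a truncated, gap-padded sequence with no comparable position are
skipped and the effective replicate count reported; in the pipeline,
proteins truncated below half the modal length are excluded from tree
leaves in the first place, since a handful of residues carries no usable
signal. The study design's 100 replicates is the default.

## Determinism and numerical choices

Every random draw flows from a single top-level seed through per-stage
derived streams (`derive_seed()`), so identical configurations give
byte-identical FASTA output and identical reports, and simulating one
library never perturbs another. Ties are broken deterministically
throughout (alignment traceback order; haplotype ordering; majority-base
ties alphabetical; NJ as implemented in ape). bp/SNP uses half-up rounding;
the pI bisection runs 60 halvings of [0, 14] (≈ 1e-17 interval), far below
the 1e-3 self-consistency the tests assert.

## Problem sizes used in the test suite

The suite favors exact, small oracles: exhaustive alignment enumeration up
to length ~7, NG86 enumeration up to 3 codons, NJ recovery on random
additive metrics up to 8 taxa. Simulation-based properties use one 489 bp
gene at 100 clones per library — Monte-Carlo density calibration over 200
seeds, error-rate calibration over 60 libraries, and robustness at the
default noise regime (error 0.001, chimera 0.05) over 100 seeds, where the
suite requires ≥ 90% median haplotype recall, ≤ 1 median false haplotype,
and zero false SNP calls in ≥ 95% of runs. These sizes were chosen as the
smallest that give stable Monte-Carlo verdicts for the properties tested.

## Known limitations

* Substitutions only: indel polymorphism is neither simulated nor called.
* Chimeras are modeled with a single template switch per molecule.
* Haplotype phasing beyond clone identity (e.g. chromosome dosage
  assignment among the 8 homologs) is out of scope.
* Consensus-class definition depends on the union SNP coordinate choice
  discussed above; fixed inter-species differences that are monomorphic
  within every species are invisible to it by construction.
* The Welch test treats per-haplotype clone supports as independent
  observations, as in the source analysis; supports within a library are
  weakly negatively correlated by the fixed library size.
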
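---
title: "siteburden: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{siteburden: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the model behind each stage, the tunable parameters and their
defaults, the numerical conventions at boundaries, what the synthetic data
generator does and does not emulate, and the design decisions that were
genuinely open.

## The screening model

The package screens for genes whose encoded proteins accumulate somatic
missense mutations in their ligand-binding sites. The underlying idea is
that binding residues — the positions that contact nucleic acids, peptides,
small molecules or ions in solved structures — are functionally critical,
so mutation clustering there suggests selection, even in genes that are
rarely mutated overall. The unit of inference is the *binding site within
one reference protein*, not the gene, which is what gives the screen power
on infrequently mutated genes.

Four stages feed the test:

**Coordinate mapping.** Genomic substitutions are placed into the spliced
CDS of each isoform of the overlapping gene (strand-aware, standard
genetic code), giving a protein position, reference and alternate amino
acid, and a derived variant class (synonymous when the amino acid is
unchanged, missense when it changes, "other" for stop-affecting changes,
which are excluded downstream). One reference isoform per gene is chosen:
the isoform that maps the largest number of *distinct* mutated protein
positions, pooling missense and synonymous calls across all cohorts; ties
go to the lowest assembly rank. Pooling across cohorts (rather than
choosing per cohort) was an open choice; we pool so that there is a single
reference sequence set and all cohorts are tested against the same
coordinates. Mutations whose stated reference allele disagrees with the
genome raise an error rather than being silently re-complemented — this is
deliberate, as silent re-complementation hides strand bookkeeping bugs.

**Binding-site transfer.** Homology hits between reference sequences and
structure chains are consumed from files (the package does not run an
aligner); identity and coverage are always recomputed from the pairwise
alignment, never trusted from the hit table. A hit is accepted when
E-value < 1e-6, identity > 0.60 over aligned columns, and coverage of the
*structure chain* > 0.80 — all strict inequalities, so a hit at exactly
60% identity is rejected. Annotated binding residues of an accepted chain
are mapped through the alignment; the whole site transfers only if more
than 90% of its binding residues align to an identical amino acid, with a
residue aligned to a gap counting as non-identical. Transferred sites of
the same ligand category sharing at least one residue are merged
transitively. Merging across categories is *not* done: category identity
must survive merging because downstream summaries are reported per
category, so a nucleic-acid site and a small-molecule site that overlap
remain two sites.

**Binding scores.** Each site position `i` is weighted by
`b_i = mean_j |Ã_ij| / |A_ij|`, the fraction of the residue's heavy atoms
within the contact radius of any ligand atom of the site's category in
structure `j`, averaged over the accepted structures that both cover
position `i` in their alignment and resolve the residue's coordinates.
Unresolved residues are excluded from the average, not zero-filled; a
structure that covers the position but has no ligand of the category
contributes a fraction of 0. The contact radius is 4.0 Å, *inclusive*
(a pair at exactly 4.0 Å counts), which makes the boundary deterministic.
Hydrogens are dropped on reading; where altloc variants exist, only the
highest-occupancy location is kept. An annotated binding residue whose
atoms never come within the radius keeps b = 0 and stays in the site: the
annotation defines membership, the score only weights it.

**The site test.** For one reference sequence in one run, let `m` be the
number of missense mutation events at its structural positions (events
keep per-sample multiplicity), and for each site

```
s_b = sum over mutated site residues i of  b_i * (#distinct samples mutated at i).
```

The null redraws `m` positions uniformly with replacement from the
sequence's structural positions and scores each replicate as the sum of
the drawn positions' binding scores (0 off-site). The empirical p-value is
the fraction of replicates scoring at least `s_b`. p-values across all
sites of a run are converted to FDRs by Benjamini–Hochberg.

Cohort-level summaries use position counts, each position counted once
regardless of recurrence: N structural positions, K binding positions, n
positions hit by the variant class under test, k binding positions hit.
The exact hypergeometric upper tail P(X ≥ k) is used for missense, the
lower tail P(X ≤ k) for SNPs (which are expected to avoid binding sites);
per-category analyses restrict K and k to one ligand category while N and
n stay global, so each category is tested against the same structural
background. A binomial companion test counts events *with* multiplicity,
with success probability q = (binding structural positions)/(structural
positions). Enrichment of curated cancer genes among significant hits is
reported as (fraction positive among selected)/(fraction positive among
background), where the background is everything with at least one mutated
binding position; the counting unit defaults to sites (with genes
available as an option) because published instance counts mix the two and
the site-level counting reproduces them.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `eValueMax` | 1e-6 | homology hit acceptance (strict <) |
| `identityMin` | 0.60 | alignment identity over aligned columns (strict >) |
| `coverageMin` | 0.80 | fraction of structure chain aligned (strict >) |
| `bindingIdentityMin` | 0.90 | identity over binding residues for transfer (strict >) |
| `contactRadius` | 4.0 Å | heavy-atom contact threshold (inclusive ≤) |
| `replicates` | 100 000 | permutation replicates R |
| `tieConvention` | `"ge"` | replicate ≥ observed counts toward p |
| `multiplicityMode` | `"events"` | m counts events, not distinct positions |
| `aggregate` | `TRUE` | pool cohorts in one run vs per-cohort runs |

## Numerical conventions

* **Ties.** "At least as extreme" is implemented as ≥ with a 1e-9
  tolerance on floating sums. This is conservative and has two pleasant
  consequences: the degenerate case where the site covers every structural
  position with b = 1 gives p = 1 exactly, and p can never be 0.
* **p floor.** A replicate count of zero reports p = 1/R, keeping p in
  (0, 1] for the BH step. With m = 0 the test returns p = 1.
* **Seeding.** One master seed; each site's test derives a child seed from
  (seed, refseq, site id) via a deterministic string hash, so per-site
  p-values do not depend on the order sites are iterated, and a
  stage-by-stage run equals the monolithic run byte for byte.
* **m vs s_b asymmetry.** m counts events with multiplicity while the
  observed s_b collapses repeated mutations of one sample at one residue
  into a single sample count, and replicates score every drawn event.
  With duplicated records this makes the test slightly conservative. The
  convention follows the definition of the score ("number of samples");
  `multiplicityMode = "positions"` is provided for sensitivity analysis.
* **Degenerate inputs.** Empty structural positions with m > 0 is an
  error; a refseq with no accepted structure match simply yields no sites;
  an empty result table writes a header-only file and reads back empty.

## What the generator emulates — and what it does not

`generateFixture` builds a fully self-consistent bundle: a genome with
multi-exon genes on both strands (codon-aligned exon boundaries so the
two-isoform models stay in frame), structures whose chains are exact
subsequences of the reference proteins, ligands placed so each annotated
binding residue attains a prescribed heavy-atom contact fraction exactly
(one ligand atom at exactly the contact radius from each contacted residue
atom; non-contacted atoms strictly beyond), scripted homology files, and
mutation cohorts in which each missense event targets a binding residue of
a driver gene with probability `enrichmentEffect` and otherwise falls
uniformly in the CDS. Residue heavy-atom counts follow the real amino
acid (4 for Gly up to 14 for Trp), which matters statistically: it gives
binding scores many distinct rational values, keeping the permutation
score distribution off a coarse lattice and the null p-values close to
uniform.

The defaults describe the benchmark conditions used throughout the tests:
20 genes, 3 drivers, two cohorts of 40 samples, effect 0.8, background
missense rate 0.05 events/residue/cohort, structures covering the central
80% of each protein. The null-calibration instance (no drivers, effect 0,
one cohort, 4 sites per gene, background rate 0.45) was sized so that a
sequence typically carries ~45 structural-position events — enough that
the "no mutation in the site" atom at p = 1 is rare and the
Kolmogorov–Smirnov comparison against the uniform is meaningful. Problem
sizes in the test-suite instances (about 560 sites for calibration, 20
generator seeds for recovery, permutation depths of 2×10^4 where the
Monte-Carlo error budget allows it) were chosen as the smallest sizes at
which the checks are statistically sharp.

What the generator does **not** emulate: trinucleotide mutational
signatures and hotspot context, copy-number change, germline
contamination, alignment error (its homology files are exact by
construction), author-numbered or insertion-coded PDB files, and
biological realism of structure geometry (only atom counts and distances
matter to the score). Passing the planted-recovery benchmark therefore
demonstrates the statistical machinery end to end — coordinate
bookkeeping, transfer gates, scoring, null calibration — but not
robustness to noisy homology or to non-uniform background mutation, which
real cohorts have and the permutation null deliberately ignores.

## Known limitations

* The permutation null assumes mutation events land uniformly over a
  sequence's structural positions; genes with strong regional mutation
  biases can inflate site scores for reasons unrelated to binding.
* Only single-nucleotide substitutions are interpreted; indels, splice
  and nonsense variants are tagged and set aside.
* Protein–protein interfaces are intentionally out of scope — interfaces
  can cover a large fraction of a protein, which would dilute the
  site-level signal the screen is built around.
* Structure coverage bounds the screen: only genes with a transferable
  ligand-bound structure can be tested at all.
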
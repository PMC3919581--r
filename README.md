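# siteburden

Most somatic mutations observed across tumour exomes are passengers; the
hard problem is flagging the genes where mutations are doing something. One
strong functional signal is *where* mutations land within a protein:
residues that bind nucleic acids, peptides, small molecules or ions are the
working parts of most proteins, and a gene whose mutations cluster in a
binding site is a good driver candidate even when the gene is rarely
mutated overall.

`siteburden` implements an interaction-based screen for such genes:

1. **Map** somatic coding mutations from genomic to protein coordinates,
   choosing one reference isoform per gene (the isoform that maps the most
   distinct mutated positions; ties go to the first isoform in the
   assembly).
2. **Annotate** each reference protein with ligand-binding sites
   transferred by homology from ligand-bound structures: hits are kept when
   E-value < 1e-6, sequence identity > 60% and structure coverage > 80%, a
   site is transferred only when identity over its binding residues exceeds
   90%, and overlapping sites of one ligand category are merged. Each
   binding residue *i* gets a weight
   *b<sub>i</sub>* = mean<sub>j</sub> |Ã<sub>ij</sub>| / |A<sub>ij</sub>|,
   where A<sub>ij</sub> are the residue's heavy atoms in covering structure
   *j* and Ã<sub>ij</sub> those within 4.0 Å of any ligand atom.
3. **Test** each binding site's burden: the observed score
   *s<sub>b</sub>* = Σ<sub>i∈site</sub> b<sub>i</sub> · (#samples with a
   missense mutation at *i*) is compared with a resampling null in which
   the sequence's *m* structural-position mutation events are redrawn
   uniformly (with replacement) over its structural positions; empirical
   p-values over 100 000 replicates are converted to FDRs by
   Benjamini–Hochberg.
4. **Summarise** at cohort level: hypergeometric tails on the
   (N, K, n, k) position counts — structural positions, binding positions,
   positions hit, binding positions hit — with the upper tail for cancer
   missense mutations and the lower tail for population SNPs, a
   frequency-aware binomial companion test, and enrichment curves of
   curated cancer genes among the significant hits.

A deterministic synthetic-data generator (`generateFixture`) emulates every
input — genome, transcript models, structures with placed ligands, homology
files, mutation cohorts, SNP tables — with planted binding-site enrichment
and a ground-truth manifest, so the entire pipeline is testable offline.

## Worked example

```r
library(siteburden)

spec <- fixtureSpec(rngSeed = 7)        # 20 genes, 3 drivers, 2 cohorts
generateFixture(spec, "bundle")

cfg <- runConfig(
  genome = "bundle/genome.fa", transcripts = "bundle/transcripts.tsv",
  mutations = "bundle/mutations.tsv", structures = "bundle/structures",
  biolip = "bundle/biolip.tsv", hits = "bundle/hits.tsv",
  snps = "bundle/snps.tsv", ccg = "bundle/ccg.txt",
  outDir = "results", replicates = 20000, seed = 11)
res <- runPipeline(cfg)

head(res$siteResults[order(res$siteResults$p_empirical), ], 5)
#>     gene site_id category  m      s_b p_empirical          fdr
#> GENE001   PEP_1      PEP 85 26.56115       5e-05 0.0003333333
#> GENE001   SMI_1      SMI 85 18.13474       5e-05 0.0003333333
#> GENE002   NUC_1      NUC 70 24.74444       5e-05 0.0003333333
#> GENE002   SMI_1      SMI 70 13.14286       5e-05 0.0003333333
#> GENE003   SMI_1      SMI 68 16.78788       5e-05 0.0003333333
```

The three planted driver genes (GENE001–GENE003) surface with site
p-values at the resolution floor (1/R = 5e-05) and FDR well below 0.1: the
permutation null asks how often a random redistribution of each gene's
mutation events over its structurally covered residues would score the
site this highly, and the planted clustering is essentially never matched.
The cohort-level counts show the directional contrast between somatic
missense mutations and SNPs:

```r
subset(res$globalCounts, category == "ALL" & test == "hypergeometric")
#>      class  tail    N   K   n  k            p
#>   missense upper 2116 236  68 39 2.923717e-21
#> synonymous upper 2116 236  74  7 7.363636e-01
#>        snp lower 2116 236 266  2 1.729638e-12
```

Of N = 2116 structurally covered positions, K = 236 are binding residues;
missense mutations hit k = 39 binding positions of n = 68 hit positions —
far more than the hypergeometric null expects (upper tail 2.9e-21) — while
SNPs avoid binding residues (lower tail 1.7e-12) and synonymous mutations
are unremarkable (p = 0.74), exactly the planted design.

A thin command-line front end with `simulate / map / annotate / site-test /
cohort-test / enrich / run` subcommands is installed at
`inst/scripts/siteburden.R`.

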
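test_that("plus-strand mutations translate through the genetic code", {
  tmp <- withr::local_tempdir()
  paths <- writeTinyGenomeTx(tmp, cds = "ATGGCCAAA", strand = "+")
  genome <- readGenome(paths$genome)
  tx <- readTranscriptModels(paths$transcripts)[1, ]

  mut <- list(chrom = "chr1", pos = 104L, ref = "G", alt = "A",
              sample = "s1", cohort = "C1")
  pm <- mapMutationToIsoform(mut, tx, genome)
  expect_equal(pm$protein_pos, 2L)
  expect_equal(pm$ref_aa, "A")  # GCC = Ala
  expect_equal(pm$alt_aa, "T")  # ACC = Thr
  expect_equal(pm$class, "missense")

  syn <- mapMutationToIsoform(list(chrom = "chr1", pos = 106L, ref = "C",
                                   alt = "A", sample = "s1",
                                   cohort = "C1"), tx, genome)
  expect_equal(syn$ref_aa, syn$alt_aa)  # GCC -> GCA, both Ala
  expect_equal(syn$class, "synonymous")

  # outside the CDS
  expect_null(mapMutationToIsoform(list(chrom = "chr1", pos = 50L,
                                        ref = "T", alt = "A",
                                        sample = "s1", cohort = "C1"),
                                   tx, genome))
  # reference mismatch is an error carrying both bases
  expect_error(mapMutationToIsoform(list(chrom = "chr1", pos = 104L,
                                         ref = "T", alt = "A",
                                         sample = "s1", cohort = "C1"),
                                    tx, genome),
               class = "siteburden_refmismatch_error")
})

test_that("minus-strand mapping agrees with independent translation", {
  tmp <- withr::local_tempdir()
  cds <- "ATGGCCAAA"
  paths <- writeTinyGenomeTx(tmp, cds = cds, strand = "-")
  genome <- readGenome(paths$genome)
  tx <- readTranscriptModels(paths$transcripts)[1, ]

  # codon 2 occupies CDS offsets 4-6 -> genomic 106,105,104 (descending);
  # transcript base G at offset 4 is top-strand C at genomic 106
  mut <- list(chrom = "chr1", pos = 106L, ref = "C", alt = "T",
              sample = "s1", cohort = "C1")
  pm <- mapMutationToIsoform(mut, tx, genome)
  expect_equal(pm$protein_pos, 2L)
  expect_equal(pm$class, "missense")

  # oracle: mutate the spliced CDS directly and translate both
  mutCds <- cds
  substr(mutCds, 4, 4) <- "A"  # complement of alt T on the transcript
  expect_equal(pm$ref_aa, substr(oracleTranslate(cds), 2, 2))
  expect_equal(pm$alt_aa, substr(oracleTranslate(mutCds), 2, 2))
})

test_that("nonsense changes are classed other", {
  tmp <- withr::local_tempdir()
  paths <- writeTinyGenomeTx(tmp, cds = "ATGTACAAA", strand = "+")
  genome <- readGenome(paths$genome)
  tx <- readTranscriptModels(paths$transcripts)[1, ]
  # TAC -> TAA (stop)
  pm <- mapMutationToIsoform(list(chrom = "chr1", pos = 106L, ref = "C",
                                  alt = "A", sample = "s1",
                                  cohort = "C1"), tx, genome)
  expect_equal(pm$alt_aa, "*")
  expect_equal(pm$class, "other")
})

test_that("isoform selection maximises mapped positions with rank ties", {
  expect_equal(selectIsoform(c(A = 3L, B = 5L), c(A = 1L, B = 2L)), "B")
  expect_equal(selectIsoform(c(A = 3L, B = 3L), c(A = 1L, B = 2L)), "A")
  # name order of the counts never matters, only the assembly rank
  expect_equal(selectIsoform(c(B = 3L, A = 3L), c(A = 2L, B = 4L)), "A")
  expect_equal(selectIsoform(c(B = 3L, A = 3L), c(A = 4L, B = 2L)), "B")
  expect_equal(selectIsoform(c(A = 0L), c(A = 1L)), "A")
})

test_that("reference-set building conserves mutations and records reasons", {
  tmp <- withr::local_tempdir()
  fx <- generateFixture(fixtureSpec(nGenes = 6L, nDrivers = 2L,
                                    cohorts = c(C1 = 10L),
                                    backgroundRate = 0.03,
                                    synonymousRate = 0.01, nSnps = 20L,
                                    nNoncoding = 4L, rngSeed = 42L),
                        file.path(tmp, "fx"))
  genome <- readGenome(fx$paths$genome)
  tx <- readTranscriptModels(fx$paths$transcripts)
  mut <- readMutations(fx$paths$mutations, "maf")
  ref <- buildReferenceSet(mut, tx, genome)

  # conservation: every input row lands in exactly one output
  expect_equal(nrow(ref$mapped) + nrow(ref$unmapped), nrow(mut))
  # planted in-CDS events all map; the non-coding decoys do not
  expect_equal(nrow(ref$mapped), fx$manifest$inCdsEvents)
  expect_equal(nrow(ref$unmapped), fx$manifest$nNoncoding)
  expect_true(all(ref$unmapped$reason == "not in CDS"))

  # protein positions never exceed the chosen isoform's length
  lens <- nchar(ref$refseqs)
  expect_true(all(ref$mapped$protein_pos <= lens[ref$mapped$gene]))

  # independent oracle: re-translate the mutated spliced CDS for every
  # mapped mutation and compare amino-acid calls and class
  txByIso <- split(tx, tx$isoform)
  for (i in seq_len(nrow(ref$mapped))) {
    pm <- ref$mapped[i, ]
    t1 <- txByIso[[pm$isoform]]
    cds <- siteburden:::splicedCds(t1, genome)
    off <- 3L * (pm$protein_pos - 1L)
    refCodon <- substr(cds, off + 1L, off + 3L)
    expect_equal(unname(Biostrings::GENETIC_CODE[refCodon]), pm$ref_aa)
    if (pm$class == "synonymous") expect_equal(pm$ref_aa, pm$alt_aa)
    if (pm$class == "missense") expect_true(pm$ref_aa != pm$alt_aa)
  }

  # strand symmetry is exercised: the fixture contains both orientations
  expect_setequal(unique(tx$strand), c("+", "-"))
})

test_that("isoform choice prefers the isoform mapping more positions", {
  tmp <- withr::local_tempdir()
  # gene with 2 isoforms; isoform 2 lacks the last CDS segment, so a
  # mutation there forces isoform 1
  fx <- generateFixture(fixtureSpec(nGenes = 3L, nDrivers = 1L,
                                    cohorts = c(C1 = 5L),
                                    backgroundRate = 0.05,
                                    synonymousRate = 0, nSnps = 5L,
                                    nNoncoding = 0L, rngSeed = 5L),
                        file.path(tmp, "fx"))
  genome <- readGenome(fx$paths$genome)
  tx <- readTranscriptModels(fx$paths$transcripts)
  mut <- readMutations(fx$paths$mutations, "maf")
  ref <- buildReferenceSet(mut, tx, genome)
  expect_true(all(grepl("\\.1$", ref$isoformMappings$chosen_isoform)))
  # all mapped mutations sit on the chosen isoforms
  chosen <- setNames(ref$isoformMappings$chosen_isoform,
                     ref$isoformMappings$gene)
  expect_true(all(ref$mapped$isoform == chosen[ref$mapped$gene]))
})
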
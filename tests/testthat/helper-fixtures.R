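# Small hand-built objects shared across tests. Everything is generated in
# code; no fixture files on disk.

heavyAtoms <- siteburden:::AA_HEAVY_ATOMS

# A chain laid out on a line: residue i centred at x = 10*(i-1), heavy atoms
# stacked along z at 0..A-1 (same geometry as the synthetic generator).
makeLineChain <- function(seqStr, structureId = "S1", chainId = "A") {
  aa <- strsplit(seqStr, "")[[1]]
  atoms <- do.call(rbind, lapply(seq_along(aa), function(i) {
    A <- heavyAtoms[[aa[i]]]
    data.frame(resno = i, aa = aa[i], atom = sprintf("C%d", seq_len(A)),
               x = 10 * (i - 1), y = 0, z = seq_len(A) - 1,
               stringsAsFactors = FALSE)
  }))
  new("StructureChain", structureId = structureId, chainId = chainId,
      sequence = seqStr, atoms = atoms)
}

makeLigand <- function(coords, ligandId = "LIG", category = "SMI") {
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  new("LigandRecord", ligandId = ligandId, category = category,
      atoms = coords)
}

makeHit <- function(refAln, chainAln, refseqId = "G1", structureId = "S1",
                    chainId = "A", eValue = 1e-10) {
  cols <- siteburden:::alignmentColumns(refAln, chainAln)
  st <- siteburden:::alignmentStats(cols)
  new("HomologyHit", refseqId = refseqId, structureId = structureId,
      chainId = chainId, eValue = eValue, pctIdentity = st$identity,
      structureCoverage = st$coverage, alignment = cols)
}

acceptedMatch <- function(...) {
  filterHits(list(makeHit(...)))[[1]]
}

makeSite <- function(refseqId, positions, b, category = "SMI",
                     siteId = paste0(category, "_1")) {
  new("MappedBindingSite", refseqId = refseqId, siteId = siteId,
      category = category, positions = as.integer(positions),
      bindingScores = stats::setNames(b, positions),
      sourceStructures = "S1_A")
}

makeSiteSet <- function(sites, structural, lengths = NULL) {
  if (is.null(lengths)) {
    lengths <- vapply(structural, max, 1L)
  }
  new("BindingSiteSet", sites = sites, structuralPositions = structural,
      refseqLengths = stats::setNames(as.integer(lengths),
                                      names(structural)))
}

protMut <- function(gene, pos, sample, class = "missense",
                    cohort = "C1") {
  data.frame(gene = gene, isoform = paste0(gene, ".1"),
             protein_pos = as.integer(pos), ref_aa = "A", alt_aa = "V",
             sample = sample, cohort = cohort, class = class,
             stringsAsFactors = FALSE)
}

# write a single-chromosome genome + one-gene transcript table; cds placed
# at position 101 on the requested strand
writeTinyGenomeTx <- function(dir, cds = "ATGGCCAAA", strand = "+",
                              gene = "G1") {
  pre <- strrep("T", 100)
  locus <- if (strand == "+") cds else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  writeLines(c(">chr1", paste0(pre, locus, strrep("A", 20))),
             file.path(dir, "genome.fa"))
  tx <- data.frame(gene = gene, isoform = paste0(gene, ".1"), rank = 1L,
                   chrom = "chr1", strand = strand,
                   segments = sprintf("101-%d", 100 + nchar(cds)))
  write.table(tx, file.path(dir, "transcripts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(genome = file.path(dir, "genome.fa"),
       transcripts = file.path(dir, "transcripts.tsv"))
}

writeMutTsv <- function(path, df) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# generate a fixture bundle and run the analysis stages in memory
runFixtureAnalysis <- function(spec, replicates = 2e4, seed = 1L,
                               dir = tempfile("fx")) {
  fx <- generateFixture(spec, dir)
  genome <- readGenome(fx$paths$genome)
  tx <- readTranscriptModels(fx$paths$transcripts)
  mut <- readMutations(fx$paths$mutations, "maf")
  ref <- buildReferenceSet(mut, tx, genome)
  pdbs <- list.files(fx$paths$structures, full.names = TRUE)
  st <- readStructures(pdbs, fx$paths$biolip)
  hits <- readHomologyHits(fx$paths$hits)
  siteSet <- annotateReference(ref$refseqs, filterHits(hits),
                               st$bindingRecords, st$chains)
  res <- testBindingSites(siteSet, ref$mapped, replicates = replicates,
                          seed = seed)
  list(fx = fx, ref = ref, siteSet = siteSet, results = res)
}

# exact permutation-null tail: full enumeration of the m-fold product
# distribution over the structural-position scores
exactPermTail <- function(bvec, m, sObs) {
  draws <- do.call(expand.grid, rep(list(bvec), m))
  mean(rowSums(draws) >= sObs - 1e-9)
}

# independent oracle: translate a codon with the standard genetic code table
oracleTranslate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}
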
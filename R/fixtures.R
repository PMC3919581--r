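AA20 <- names(AA_HEAVY_ATOMS)

# reverse genetic code: codons per amino acid (stop excluded)
codonsFor <- function(aa) {
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
}

#' Specification of a synthetic fixture bundle
#'
#' Collects the knobs of the synthetic-data generator: cohort sizes,
#' per-residue background mutation rate, the probability that a mutation
#' event is planted into a binding residue of a driver gene
#' (\code{enrichmentEffect}), gene/structure geometry, and the RNG seed.
#' Defaults describe a small two-cohort study with 20 genes of which 3 are
#' drivers carrying strongly enriched binding sites.
#'
#' @param nGenes number of genes.
#' @param isoformsPerGene 1 or 2 isoforms per gene (the second isoform drops
#'   the last CDS segment).
#' @param proteinLength length-2 integer range of protein lengths (residues).
#' @param sitesPerGene binding sites planted per gene.
#' @param siteSize length-2 integer range of binding-site sizes (residues).
#' @param categoryWeights named weights for sampling the ligand category of
#'   each site (proportional to the representation of small-molecule/ion,
#'   peptide and nucleic-acid sites among structural entries).
#' @param nDrivers number of driver genes (the first \code{nDrivers} genes).
#' @param enrichmentEffect probability in [0,1] that a missense event
#'   targets a binding residue of a driver gene instead of a uniform CDS
#'   position.
#' @param cohorts named integer vector: samples per cohort.
#' @param backgroundRate expected missense events per residue per cohort.
#' @param synonymousRate expected synonymous events per residue per cohort
#'   (always placed uniformly).
#' @param nSnps number of SNP rows (protein coordinates).
#' @param snpOffsiteBias probability that a SNP is placed on a structural
#'   non-binding position instead of a uniform position.
#' @param nNoncoding mutation rows planted outside any CDS (exercises the
#'   unmapped ledger).
#' @param windowFraction fraction of each protein covered by its structure
#'   chain (centred window).
#' @param rngSeed integer seed; the bundle is a deterministic function of
#'   the spec.
#' @return a validated list of class \code{"fixtureSpec"}.
#' @export
fixtureSpec <- function(nGenes = 20L, isoformsPerGene = 2L,
                        proteinLength = c(100L, 160L), sitesPerGene = 2L,
                        siteSize = c(4L, 8L),
                        categoryWeights = c(SMI = 0.82, PEP = 0.23,
                                            NUC = 0.14),
                        nDrivers = 3L, enrichmentEffect = 0.8,
                        cohorts = c(C1 = 40L, C2 = 40L),
                        backgroundRate = 0.05, synonymousRate = 0.02,
                        nSnps = 300L, snpOffsiteBias = 0.9,
                        nNoncoding = 5L, windowFraction = 0.8,
                        rngSeed = 1L) {
  spec <- list(nGenes = as.integer(nGenes),
               isoformsPerGene = as.integer(isoformsPerGene),
               proteinLength = as.integer(proteinLength),
               sitesPerGene = as.integer(sitesPerGene),
               siteSize = as.integer(siteSize),
               categoryWeights = categoryWeights,
               nDrivers = as.integer(nDrivers),
               enrichmentEffect = enrichmentEffect,
               cohorts = cohorts, backgroundRate = backgroundRate,
               synonymousRate = synonymousRate, nSnps = as.integer(nSnps),
               snpOffsiteBias = snpOffsiteBias,
               nNoncoding = as.integer(nNoncoding),
               windowFraction = windowFraction,
               rngSeed = as.integer(rngSeed))
  stopifnot(spec$nGenes >= 1, spec$isoformsPerGene %in% 1:2,
            spec$nDrivers >= 0, spec$nDrivers <= spec$nGenes,
            spec$enrichmentEffect >= 0, spec$enrichmentEffect <= 1,
            spec$snpOffsiteBias >= 0, spec$snpOffsiteBias <= 1,
            spec$backgroundRate >= 0, spec$synonymousRate >= 0,
            spec$windowFraction > 0, spec$windowFraction <= 1,
            all(spec$cohorts >= 1), all(names(spec$categoryWeights) %in%
                                          LIGAND_CATEGORIES))
  class(spec) <- "fixtureSpec"
  spec
}

#' Ligand-atom placement realising a prescribed contact fraction
#'
#' Given a residue whose heavy atoms sit at (0, 0, z) for z = 0..nAtoms-1
#' (one Angstrom apart), returns ligand atom offsets such that exactly
#' \code{fraction * nAtoms} residue atoms lie within the contact radius
#' (inclusive) of some ligand atom and all other residue atoms lie strictly
#' beyond it: one ligand atom sits at the contact radius in y from each of
#' the top k residue atoms, so every contact distance is exactly the radius
#' and every non-contact distance exceeds it.
#'
#' @param nAtoms residue heavy-atom count.
#' @param fraction target contact fraction; \code{fraction * nAtoms} must be
#'   an integer.
#' @param radius contact radius in Angstrom.
#' @return a matrix of ligand atom offsets (k x 3) in the residue frame.
#' @export
placeLigandForFraction <- function(nAtoms, fraction,
                                   radius = CONTACT_RADIUS) {
  k <- fraction * nAtoms
  if (abs(k - round(k)) > 1e-9 || fraction < 0 || fraction > 1) {
    sbStop("siteburden_usage_error",
           "fraction %.4f times %d atoms is not an integer", fraction,
           nAtoms)
  }
  k <- as.integer(round(k))
  if (k == 0L) return(cbind(x = 0, y = 1000, z = 0))
  zTop <- seq.int(nAtoms - k, nAtoms - 1L)
  cbind(x = 0, y = radius, z = as.numeric(zTop))
}

# Internal: construct the gene/structure layout (pure function of the RNG
# state). Returns everything plantCohort and the writers need.
buildLayout <- function(spec) {
  genes <- list()
  genomeParts <- character(0)
  cursor <- 0L
  catW <- spec$categoryWeights / sum(spec$categoryWeights)

  randSeq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }

  for (g in seq_len(spec$nGenes)) {
    name <- sprintf("GENE%03d", g)
    L <- sample(seq(spec$proteinLength[1], spec$proteinLength[2]), 1)
    protein <- paste(c("M", sample(AA20, L - 1L, replace = TRUE)),
                     collapse = "")
    codons <- vapply(strsplit(protein, "")[[1]], function(aa) {
      sample(codonsFor(aa), 1)
    }, "")
    cds <- paste(codons, collapse = "")
    # three CDS segments at codon boundaries
    c1 <- max(1L, L %/% 3L)
    c2 <- max(1L, L %/% 3L)
    segCodons <- c(c1, c2, L - c1 - c2)
    segSeqs <- character(3)
    off <- 0L
    for (s in 1:3) {
      segSeqs[s] <- substr(cds, 3L * off + 1L, 3L * (off + segCodons[s]))
      off <- off + segCodons[s]
    }
    strand <- if (runif(1) < 0.5) "+" else "-"
    intron1 <- randSeq(20L)
    intron2 <- randSeq(20L)
    gap <- randSeq(30L)
    genomeParts <- c(genomeParts, gap)
    cursor <- cursor + 30L
    segLens <- 3L * segCodons
    if (strand == "+") {
      locus <- paste0(segSeqs[1], intron1, segSeqs[2], intron2, segSeqs[3])
      starts <- cursor + c(1L, 1L + segLens[1] + 20L,
                           1L + segLens[1] + 20L + segLens[2] + 20L)
      segs <- cbind(start = starts, end = starts + segLens - 1L)
    } else {
      rc <- function(s) as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
      locus <- paste0(rc(segSeqs[3]), intron1, rc(segSeqs[2]), intron2,
                      rc(segSeqs[1]))
      s3 <- cursor + 1L
      s2 <- s3 + segLens[3] + 20L
      s1 <- s2 + segLens[2] + 20L
      segs <- cbind(start = c(s1, s2, s3),
                    end = c(s1 + segLens[1] - 1L, s2 + segLens[2] - 1L,
                            s3 + segLens[3] - 1L))
    }
    genomeParts <- c(genomeParts, locus)
    cursor <- cursor + nchar(locus)

    # structure window and binding sites (protein coordinates)
    wStart <- max(1L, floor(L * (1 - spec$windowFraction) / 2) + 1L)
    wEnd <- min(L, wStart + as.integer(round(L * spec$windowFraction)) - 1L)
    sites <- list()
    used <- integer(0)
    for (s in seq_len(spec$sitesPerGene)) {
      size <- sample(seq(spec$siteSize[1], spec$siteSize[2]), 1)
      ok <- FALSE
      for (try in 1:50) {
        st <- sample(seq(wStart, wEnd - size + 1L), 1)
        pos <- st:(st + size - 1L)
        if (!length(intersect(pos, used))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) next
      used <- c(used, pos)
      aaVec <- strsplit(protein, "")[[1]][pos]
      nA <- AA_HEAVY_ATOMS[aaVec]
      kContacts <- vapply(nA, function(a) sample.int(a, 1), 1L)
      sites[[length(sites) + 1L]] <- list(
        category = sample(names(catW), 1, prob = catW),
        positions = pos, b = unname(kContacts / nA),
        kContacts = unname(kContacts))
    }
    genes[[name]] <- list(
      name = name, protein = protein, L = L, strand = strand,
      segments = segs, segCodons = segCodons, cds = cds,
      wStart = wStart, wEnd = wEnd, sites = sites,
      structureId = sprintf("STR%03d", g))
  }
  list(genes = genes, genome = paste(genomeParts, collapse = ""),
       chrom = "chr1")
}

# protein position -> genomic position of the base at codon offset `within`
proteinPosToGenomic <- function(gene, pos, within) {
  offset <- 3L * (pos - 1L) + within              # 1-based CDS offset
  cum <- c(0L, cumsum(3L * gene$segCodons))
  s <- findInterval(offset - 1L, cum, rightmost.closed = FALSE)
  inSeg <- offset - cum[s]
  seg <- gene$segments[s, ]
  if (gene$strand == "+") unname(seg["start"] + inSeg - 1L)
  else unname(seg["end"] - inSeg + 1L)
}

# single-base codon substitutions of `protein` position realising `class`
pickSubstitution <- function(gene, pos, class) {
  codon <- substr(gene$cds, 3L * pos - 2L, 3L * pos)
  opts <- list()
  refAA <- Biostrings::GENETIC_CODE[[codon]]
  for (within in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, within, within))) {
      alt <- codon
      substr(alt, within, within) <- nt
      altAA <- Biostrings::GENETIC_CODE[[alt]]
      cls <- if (altAA == "*" || refAA == "*") "other"
             else if (altAA == refAA) "synonymous" else "missense"
      if (cls == class) {
        opts[[length(opts) + 1L]] <- list(within = within, alt = nt)
      }
    }
  }
  if (!length(opts)) return(NULL)
  opts[[sample.int(length(opts), 1)]]
}

#' Plant one cohort's mutation events
#'
#' Draws each missense event as: with probability \code{effect}, a uniform
#' binding residue of a uniform driver gene; otherwise a uniform CDS
#' position across all genes (length-weighted). The nucleotide change is
#' chosen among the single-base substitutions of the codon realising the
#' requested class; synonymous control events are always uniform.
#'
#' @param layout gene layout (element \code{layout} of
#'   \code{\link{generateFixture}}'s return value).
#' @param cohort cohort label.
#' @param nSamples samples in the cohort.
#' @param nEvents missense events to plant.
#' @param nSynEvents synonymous events to plant.
#' @param effect probability of targeting a driver binding residue.
#' @param drivers character vector of driver gene names.
#' @return list with \code{mutations} (genomic mutation data.frame) and
#'   \code{truth} (per-event gene/protein position/on-site flag).
#' @export
plantCohort <- function(layout, cohort, nSamples, nEvents, nSynEvents,
                        effect, drivers) {
  genes <- layout$genes
  lens <- vapply(genes, `[[`, 1L, "L")
  driverPool <- do.call(rbind, lapply(drivers, function(g) {
    do.call(rbind, lapply(genes[[g]]$sites, function(s) {
      data.frame(gene = g, pos = s$positions)
    }))
  }))
  sampleIds <- sprintf("%s_S%03d", cohort, seq_len(nSamples))

  rows <- list()
  truth <- list()
  addEvent <- function(gene, pos, class) {
    sub <- pickSubstitution(genes[[gene]], pos, class)
    if (is.null(sub)) return(FALSE)
    gpos <- proteinPosToGenomic(genes[[gene]], pos, sub$within)
    refTop <- substr(layout$genome, gpos, gpos)
    altTop <- if (genes[[gene]]$strand == "-") complementBase(sub$alt)
              else sub$alt
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = layout$chrom, pos = gpos, ref = refTop, alt = altTop,
      sample = sample(sampleIds, 1), class = class, cohort = cohort,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      gene = gene, protein_pos = pos, class = class,
      onDriverSite = !is.null(driverPool) && class == "missense" &&
        any(driverPool$gene == gene & driverPool$pos == pos),
      stringsAsFactors = FALSE)
    TRUE
  }

  n <- 0L
  while (n < nEvents) {
    if (!is.null(driverPool) && nrow(driverPool) && runif(1) < effect) {
      i <- sample.int(nrow(driverPool), 1)
      ok <- addEvent(driverPool$gene[i], driverPool$pos[i], "missense")
    } else {
      g <- sample(names(genes), 1, prob = lens)
      ok <- addEvent(g, sample.int(lens[[g]], 1), "missense")
    }
    if (ok) n <- n + 1L
  }
  n <- 0L
  while (n < nSynEvents) {
    g <- sample(names(genes), 1, prob = lens)
    if (addEvent(g, sample.int(lens[[g]], 1), "synonymous")) n <- n + 1L
  }
  list(mutations = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Generate a complete synthetic input bundle
#'
#' Writes a self-consistent toy data set to \code{dir}: genome FASTA,
#' transcript models, structure coordinate files with placed ligands,
#' binding-annotation TSV, homology hits with pairwise alignments, mutation
#' cohorts with planted binding-site enrichment, a protein-coordinate SNP
#' table, a cancer-gene list (the drivers), and a JSON ground-truth
#' manifest. The bundle is a deterministic function of the spec.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the ground-truth \code{manifest}, the
#'   internal \code{layout}, and the paths of all written files.
#' @export
generateFixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "structures"), showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)

  withSeed(spec$rngSeed, {
    layout <- buildLayout(spec)
    genes <- layout$genes
    drivers <- names(genes)[seq_len(spec$nDrivers)]

    # genome
    genomePath <- file.path(dir, "genome.fa")
    writeLines(c(paste0(">", layout$chrom),
                 substring(layout$genome,
                           seq(1, nchar(layout$genome), 70),
                           pmin(seq(70, nchar(layout$genome) + 69, 70),
                                nchar(layout$genome)))),
               genomePath)

    # transcripts (isoform 2 drops the last CDS segment)
    txRows <- list()
    for (g in names(genes)) {
      ge <- genes[[g]]
      txRows[[length(txRows) + 1L]] <- data.frame(
        gene = g, isoform = paste0(g, ".1"), rank = 1L,
        chrom = layout$chrom, strand = ge$strand,
        segments = paste(sprintf("%d-%d", ge$segments[, 1],
                                 ge$segments[, 2]), collapse = ","),
        stringsAsFactors = FALSE)
      if (spec$isoformsPerGene == 2L) {
        txRows[[length(txRows) + 1L]] <- data.frame(
          gene = g, isoform = paste0(g, ".2"), rank = 2L,
          chrom = layout$chrom, strand = ge$strand,
          segments = paste(sprintf("%d-%d", ge$segments[1:2, 1],
                                   ge$segments[1:2, 2]), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    txPath <- file.path(dir, "transcripts.tsv")
    writeTsv(do.call(rbind, txRows), txPath)

    # structures, binding TSV, homology files
    biolipRows <- list()
    hitRows <- list()
    for (g in names(genes)) {
      ge <- genes[[g]]
      chainSeq <- substr(ge$protein, ge$wStart, ge$wEnd)
      chainAA <- strsplit(chainSeq, "")[[1]]
      recs <- list()
      serial <- 0L
      for (j in seq_along(chainAA)) {
        A <- AA_HEAVY_ATOMS[[chainAA[j]]]
        recs[[length(recs) + 1L]] <- data.frame(
          type = "ATOM", atom = sprintf("C%d", seq_len(A)),
          resid = names(STANDARD_AA3)[STANDARD_AA3 == chainAA[j]][1],
          chain = "A", resno = j, x = 10 * (j - 1), y = 0,
          z = seq_len(A) - 1, elem = "C", stringsAsFactors = FALSE)
      }
      for (si in seq_along(ge$sites)) {
        s <- ge$sites[[si]]
        ligId <- c(SMI = "LIG", PEP = "PEP", NUC = "DA")[[s$category]]
        chainIdx <- s$positions - ge$wStart + 1L
        ligAtoms <- lapply(seq_along(chainIdx), function(q) {
          j <- chainIdx[q]
          A <- AA_HEAVY_ATOMS[[chainAA[j]]]
          off <- placeLigandForFraction(A, s$kContacts[q] / A)
          data.frame(type = "HETATM",
                     atom = sprintf("O%d", seq_len(nrow(off))),
                     resid = ligId, chain = "L", resno = si,
                     x = 10 * (j - 1) + off[, 1], y = off[, 2],
                     z = off[, 3], elem = "O", stringsAsFactors = FALSE)
        })
        recs <- c(recs, ligAtoms)
        biolipRows[[length(biolipRows) + 1L]] <- data.frame(
          structure_id = ge$structureId, chain_id = "A",
          ligand_id = ligId, ligand_chain = "L", ligand_resno = si,
          category = s$category,
          binding_residues = paste(chainIdx, collapse = ";"),
          stringsAsFactors = FALSE)
      }
      writePdbFile(file.path(dir, "structures",
                             paste0(ge$structureId, ".pdb")),
                   do.call(rbind, recs))

      alnFile <- sprintf("alignments/%s_%s_A.afa", g, ge$structureId)
      refAln <- ge$protein
      chainAln <- paste0(strrep("-", ge$wStart - 1L), chainSeq,
                         strrep("-", ge$L - ge$wEnd))
      writeLines(c(paste0(">", g), refAln,
                   paste0(">", ge$structureId, "_A"), chainAln),
                 file.path(dir, alnFile))
      hitRows[[length(hitRows) + 1L]] <- data.frame(
        refseq_id = g, structure_id = ge$structureId, chain_id = "A",
        e_value = 1e-30, pct_identity = 1, coverage = 1,
        aln_file = alnFile, stringsAsFactors = FALSE)
    }
    biolipPath <- file.path(dir, "biolip.tsv")
    writeTsv(do.call(rbind, biolipRows), biolipPath)
    hitsPath <- file.path(dir, "hits.tsv")
    writeTsv(do.call(rbind, hitRows), hitsPath)

    # mutation cohorts
    totalAA <- sum(vapply(genes, `[[`, 1L, "L"))
    mutRows <- list()
    truthRows <- list()
    for (co in names(spec$cohorts)) {
      planted <- plantCohort(layout, co, spec$cohorts[[co]],
                             nEvents = max(0L, round(spec$backgroundRate *
                                                       totalAA)),
                             nSynEvents = max(0L, round(spec$synonymousRate *
                                                          totalAA)),
                             effect = spec$enrichmentEffect,
                             drivers = drivers)
      mutRows[[co]] <- planted$mutations
      planted$truth$cohort <- co
      truthRows[[co]] <- planted$truth
    }
    # non-coding decoys (first gene's first intron / upstream gap)
    if (spec$nNoncoding > 0L) {
      ge <- genes[[1]]
      seg <- ge$segments[order(ge$segments[, 1]), ]
      intronPos <- sample(seq(seg[1, 2] + 1L, seg[2, 1] - 1L),
                          spec$nNoncoding, replace = TRUE)
      refs <- vapply(intronPos, function(p) {
        substr(layout$genome, p, p)
      }, "")
      alts <- vapply(refs, function(r) {
        sample(setdiff(c("A", "C", "G", "T"), r), 1)
      }, "")
      mutRows[["noncoding"]] <- data.frame(
        chrom = layout$chrom, pos = intronPos, ref = refs, alt = alts,
        sample = sprintf("%s_S%03d", names(spec$cohorts)[1], 1L),
        class = "missense", cohort = names(spec$cohorts)[1],
        stringsAsFactors = FALSE)
    }
    mutations <- do.call(rbind, unname(mutRows))
    rownames(mutations) <- NULL
    mutPath <- file.path(dir, "mutations.tsv")
    writeTsv(mutations, mutPath)

    # SNPs in protein coordinates, biased away from binding residues
    structNonBinding <- do.call(rbind, lapply(names(genes), function(g) {
      ge <- genes[[g]]
      sitePos <- unlist(lapply(ge$sites, `[[`, "positions"))
      pos <- setdiff(ge$wStart:ge$wEnd, sitePos)
      data.frame(gene = g, pos = pos)
    }))
    lens <- vapply(genes, `[[`, 1L, "L")
    snpRows <- lapply(seq_len(spec$nSnps), function(i) {
      if (runif(1) < spec$snpOffsiteBias) {
        j <- sample.int(nrow(structNonBinding), 1)
        data.frame(gene = structNonBinding$gene[j],
                   protein_pos = structNonBinding$pos[j],
                   id = sprintf("snp%04d", i), stringsAsFactors = FALSE)
      } else {
        g <- sample(names(genes), 1, prob = lens)
        data.frame(gene = g, protein_pos = sample.int(lens[[g]], 1),
                   id = sprintf("snp%04d", i), stringsAsFactors = FALSE)
      }
    })
    snpPath <- file.path(dir, "snps.tsv")
    writeTsv(do.call(rbind, snpRows), snpPath)

    # cancer-gene list: the drivers
    ccgPath <- file.path(dir, "ccg.txt")
    writeLines(drivers, ccgPath)

    truth <- do.call(rbind, unname(truthRows))
    manifest <- list(
      rngSeed = spec$rngSeed, drivers = drivers,
      genes = lapply(genes, function(ge) {
        list(name = ge$name, length = ge$L, strand = ge$strand,
             structureId = ge$structureId,
             structuralWindow = c(ge$wStart, ge$wEnd),
             sites = lapply(ge$sites, function(s) {
               list(category = s$category, positions = s$positions,
                    b = s$b)
             }))
      }),
      nPlantedEvents = nrow(truth),
      nOnDriverSite = sum(truth$onDriverSite),
      nNoncoding = spec$nNoncoding,
      inCdsEvents = nrow(truth),
      eventTruth = truth)
    manifestPath <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    invisible(list(manifest = manifest, layout = layout,
                   paths = list(genome = genomePath, transcripts = txPath,
                                biolip = biolipPath, hits = hitsPath,
                                mutations = mutPath, snps = snpPath,
                                ccg = ccgPath, manifest = manifestPath,
                                structures = file.path(dir, "structures"),
                                dir = dir)))
  })
}
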
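#' Serialise / restore a BindingSiteSet as TSV
#'
#' \code{writeBindingSiteSet} writes two TSVs: the sites table (refseq,
#' site_id, category, semicolon-separated \code{position:score} pairs,
#' source structures) and the structural-coverage table (refseq, protein
#' length, covered positions). \code{readBindingSiteSet} restores the
#' object; the pair is the on-disk contract between the annotation and
#' testing stages.
#'
#' @param siteSet a \linkS4class{BindingSiteSet}.
#' @param sitesPath,structuralPath output/input TSV paths.
#' @param provenance optional comment lines.
#' @export
writeBindingSiteSet <- function(siteSet, sitesPath, structuralPath,
                                provenance = NULL) {
  sites <- bindingSites(siteSet)
  df <- if (length(sites)) {
    do.call(rbind, lapply(sites, function(s) {
      data.frame(refseq = s@refseqId, site_id = s@siteId,
                 category = s@category,
                 positions = paste(sprintf("%d:%s", s@positions,
                   formatC(s@bindingScores[as.character(s@positions)],
                           digits = 15, format = "g")), collapse = ";"),
                 sources = paste(s@sourceStructures, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(refseq = character(0), site_id = character(0),
               category = character(0), positions = character(0),
               sources = character(0))
  }
  df <- df[order(df$refseq, df$site_id), , drop = FALSE]
  writeTsvWithHeader(df, sitesPath, provenance)
  sp <- structuralPositions(siteSet)
  sdf <- data.frame(refseq = names(sp),
                    length = unname(siteSet@refseqLengths[names(sp)]),
                    positions = vapply(sp, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  sdf <- sdf[order(sdf$refseq), , drop = FALSE]
  writeTsvWithHeader(sdf, structuralPath, provenance)
  invisible(sitesPath)
}

#' @rdname writeBindingSiteSet
#' @export
readBindingSiteSet <- function(sitesPath, structuralPath) {
  sdf <- read.delim(structuralPath, sep = "\t", comment.char = "#",
                    colClasses = "character")
  structural <- setNames(lapply(sdf$positions, function(p) {
    as.integer(strsplit(p, ";")[[1]])
  }), sdf$refseq)
  lengths <- setNames(as.integer(sdf$length), sdf$refseq)
  df <- read.delim(sitesPath, sep = "\t", comment.char = "#",
                   colClasses = "character")
  sites <- lapply(seq_len(nrow(df)), function(i) {
    pairs <- strsplit(strsplit(df$positions[i], ";")[[1]], ":")
    pos <- as.integer(vapply(pairs, `[[`, "", 1))
    b <- as.numeric(vapply(pairs, `[[`, "", 2))
    new("MappedBindingSite", refseqId = df$refseq[i],
        siteId = df$site_id[i], category = df$category[i],
        positions = pos, bindingScores = setNames(b, pos),
        sourceStructures = strsplit(df$sources[i], ";")[[1]])
  })
  new("BindingSiteSet", sites = sites, structuralPositions = structural,
      refseqLengths = lengths)
}

writeTsvWithHeader <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) {
      formatC(x, digits = 15, format = "g")
    })
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  }
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles input/output paths, filter thresholds (defaults: E-value 1e-6,
#' identity 0.60, structure coverage 0.80, binding-residue identity 0.90,
#' contact radius 4.0 Angstrom), permutation settings and mode flags, with
#' validation up front.
#'
#' @param genome,transcripts,mutations,biolip,hits input paths;
#'   \code{structures} is a directory of PDB files.
#' @param snps optional protein-coordinate SNP table path (NULL to skip).
#' @param ccg optional gene-list path (NULL to skip enrichment).
#' @param outDir output directory.
#' @param eValueMax,identityMin,coverageMin,bindingIdentityMin,contactRadius
#'   stage thresholds.
#' @param replicates,seed permutation settings.
#' @param aggregate TRUE pools all cohorts in one site test; FALSE runs each
#'   cohort separately.
#' @param tieConvention,multiplicityMode permutation switches (see
#'   \code{\link{testBindingSites}}).
#' @return validated config list of class \code{"runConfig"}.
#' @export
runConfig <- function(genome, transcripts, mutations, structures, biolip,
                      hits, snps = NULL, ccg = NULL, outDir,
                      eValueMax = 1e-6, identityMin = 0.60,
                      coverageMin = 0.80, bindingIdentityMin = 0.90,
                      contactRadius = 4.0, replicates = 1e5, seed = 1L,
                      aggregate = TRUE, tieConvention = "ge",
                      multiplicityMode = "events") {
  cfg <- list(genome = genome, transcripts = transcripts,
              mutations = mutations, structures = structures,
              biolip = biolip, hits = hits, snps = snps, ccg = ccg,
              outDir = outDir, eValueMax = eValueMax,
              identityMin = identityMin, coverageMin = coverageMin,
              bindingIdentityMin = bindingIdentityMin,
              contactRadius = contactRadius,
              replicates = as.integer(replicates), seed = as.integer(seed),
              aggregate = isTRUE(aggregate),
              tieConvention = tieConvention,
              multiplicityMode = multiplicityMode)
  if (cfg$eValueMax <= 0 ||
      cfg$identityMin < 0 || cfg$identityMin > 1 ||
      cfg$coverageMin < 0 || cfg$coverageMin > 1 ||
      cfg$bindingIdentityMin < 0 || cfg$bindingIdentityMin > 1 ||
      cfg$contactRadius <= 0 || cfg$replicates < 1) {
    sbStop("siteburden_config_error", "threshold outside documented range")
  }
  if (!cfg$tieConvention %in% c("ge", "gt") ||
      !cfg$multiplicityMode %in% c("events", "positions")) {
    sbStop("siteburden_config_error", "unknown mode flag")
  }
  class(cfg) <- "runConfig"
  cfg
}

provenanceOf <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- cfg[setdiff(names(cfg), "outDir")]   # hash covers the analysis,
                                              # not where results land
  writeLines(vapply(cfg[order(names(cfg))], function(x) {
    paste(as.character(x), collapse = ",")
  }, ""), tmp)
  hash <- unname(tools::md5sum(tmp))
  sprintf("siteburden %s; seed=%d; config=%s",
          as.character(utils::packageVersion("siteburden")), cfg$seed, hash)
}

outPath <- function(cfg, name) file.path(cfg$outDir, name)

#' Pipeline stages
#'
#' Each stage reads the previous stage's files and writes its own, so stages
#' can be run standalone; \code{\link{runPipeline}} composes them. Outputs
#' carry a provenance comment (package version, seed, config hash).
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return each stage invisibly returns its main result object.
#' @export
stageMap <- function(cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  genome <- readGenome(cfg$genome)
  tx <- readTranscriptModels(cfg$transcripts)
  mut <- readMutations(cfg$mutations, dialect = "maf")
  ref <- buildReferenceSet(mut, tx, genome)
  prov <- provenanceOf(cfg)
  writeTsvWithHeader(ref$mapped, outPath(cfg, "mapped.tsv"), prov)
  writeTsvWithHeader(ref$unmapped, outPath(cfg, "unmapped.tsv"), prov)
  writeTsvWithHeader(ref$isoformMappings, outPath(cfg, "isoform_map.tsv"),
                     prov)
  writeLines(as.vector(rbind(paste0(">", names(ref$refseqs)), ref$refseqs)),
             outPath(cfg, "refseqs.fa"))
  invisible(ref)
}

#' @rdname stageMap
#' @export
stageAnnotate <- function(cfg) {
  refFa <- Biostrings::readAAStringSet(outPath(cfg, "refseqs.fa"))
  refseqs <- setNames(as.character(refFa), names(refFa))
  pdbs <- list.files(cfg$structures, pattern = "\\.(pdb|ent)$",
                     full.names = TRUE)
  st <- readStructures(pdbs, cfg$biolip)
  hits <- readHomologyHits(cfg$hits)
  matches <- filterHits(hits, cfg$eValueMax, cfg$identityMin,
                        cfg$coverageMin)
  siteSet <- annotateReference(refseqs, matches, st$bindingRecords,
                               st$chains, cfg$bindingIdentityMin,
                               cfg$contactRadius)
  writeBindingSiteSet(siteSet, outPath(cfg, "sites.tsv"),
                      outPath(cfg, "structural.tsv"), provenanceOf(cfg))
  invisible(siteSet)
}

#' @rdname stageMap
#' @export
stageSiteTest <- function(cfg) {
  siteSet <- readBindingSiteSet(outPath(cfg, "sites.tsv"),
                                outPath(cfg, "structural.tsv"))
  mapped <- read.delim(outPath(cfg, "mapped.tsv"), sep = "\t",
                       comment.char = "#", stringsAsFactors = FALSE)
  prov <- provenanceOf(cfg)
  prov <- c(prov, sprintf("replicates=%d; tie=%s; multiplicity=%s",
                          cfg$replicates, cfg$tieConvention,
                          cfg$multiplicityMode))
  if (cfg$aggregate) {
    res <- testBindingSites(siteSet, mapped, replicates = cfg$replicates,
                            seed = cfg$seed,
                            tieConvention = cfg$tieConvention,
                            multiplicityMode = cfg$multiplicityMode)
  } else {
    res <- do.call(rbind, lapply(sort(unique(mapped$cohort)), function(co) {
      testBindingSites(siteSet, mapped, replicates = cfg$replicates,
                       seed = cfg$seed, cohort = co,
                       tieConvention = cfg$tieConvention,
                       multiplicityMode = cfg$multiplicityMode)
    }))
  }
  writeSiteResults(res, outPath(cfg, "site_results.tsv"), prov)
  invisible(res)
}

#' @rdname stageMap
#' @export
stageCohortTest <- function(cfg) {
  siteSet <- readBindingSiteSet(outPath(cfg, "sites.tsv"),
                                outPath(cfg, "structural.tsv"))
  mapped <- read.delim(outPath(cfg, "mapped.tsv"), sep = "\t",
                       comment.char = "#", stringsAsFactors = FALSE)
  classes <- list(missense = "upper", synonymous = "upper")
  rows <- list()
  addRow <- function(label, category, counts, tail) {
    p <- hypergeomTail(counts, tail)
    rows[[length(rows) + 1L]] <<- data.frame(
      class = label, category = if (is.null(category)) "ALL" else category,
      tail = tail, N = counts$N, K = counts$K, n = counts$n, k = counts$k,
      p = p, stringsAsFactors = FALSE)
  }
  for (cls in names(classes)) {
    v <- mapped[mapped$class == cls, , drop = FALSE]
    for (cat in c(list(NULL), as.list(LIGAND_CATEGORIES))) {
      addRow(cls, cat, assembleCounts(siteSet, v, cat), classes[[cls]])
    }
  }
  if (!is.null(cfg$snps)) {
    snps <- readMutations(cfg$snps, dialect = "protein")
    for (cat in c(list(NULL), as.list(LIGAND_CATEGORIES))) {
      addRow("snp", cat, assembleCounts(siteSet, snps, cat), "lower")
    }
  }
  # frequency-aware binomial companion test (events with multiplicity)
  sitePos <- lapply(split(bindingSites(siteSet),
                          vapply(bindingSites(siteSet), slot, "",
                                 "refseqId")),
                    function(ss) unique(unlist(lapply(ss, slot,
                                                      "positions"))))
  sp <- structuralPositions(siteSet)
  q <- sum(lengths(sitePos)) / sum(lengths(sp))
  binomRows <- lapply(c("missense", "synonymous"), function(cls) {
    v <- mapped[mapped$class == cls, , drop = FALSE]
    onStruct <- vapply(seq_len(nrow(v)), function(i) {
      v$protein_pos[i] %in% sp[[v$gene[i]]]
    }, TRUE)
    onBind <- vapply(seq_len(nrow(v)), function(i) {
      v$protein_pos[i] %in% sitePos[[v$gene[i]]]
    }, TRUE)
    data.frame(class = cls, category = "ALL", tail = "upper",
               N = NA, K = NA, n = sum(onStruct), k = sum(onBind),
               p = binomialFrequencyTest(sum(onBind), sum(onStruct), q),
               stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, c(rows, binomRows))
  counts$test <- c(rep("hypergeometric", length(rows)),
                   rep("binomial_frequency", length(binomRows)))
  writeTsvWithHeader(counts, outPath(cfg, "global_counts.tsv"),
                     provenanceOf(cfg))
  invisible(counts)
}

#' @rdname stageMap
#' @export
stageEnrich <- function(cfg) {
  if (is.null(cfg$ccg)) return(invisible(NULL))
  res <- readSiteResults(outPath(cfg, "site_results.tsv"))
  ccg <- readGeneList(cfg$ccg)
  curve <- ccgEnrichmentCurve(res, ccg)
  writeTsvWithHeader(curve, outPath(cfg, "enrichment_curve.tsv"),
                     provenanceOf(cfg))
  invisible(curve)
}

#' Run the full pipeline
#'
#' Executes map, annotate, site-test, cohort-test and enrich in order.
#' Running the stages individually on the same config produces byte-wise
#' the same files.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return invisibly, a list with the site results, global counts and
#'   enrichment curve.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "runConfig"))
  for (f in c("genome", "transcripts", "mutations", "biolip", "hits")) {
    if (!file.exists(cfg[[f]])) {
      sbStop("siteburden_config_error", "input %s not found: %s", f,
             cfg[[f]])
    }
  }
  stageMap(cfg)
  stageAnnotate(cfg)
  res <- stageSiteTest(cfg)
  counts <- stageCohortTest(cfg)
  curve <- stageEnrich(cfg)
  invisible(list(siteResults = res, globalCounts = counts,
                 enrichmentCurve = curve))
}
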
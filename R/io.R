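#' Read a somatic mutation or SNP table
#'
#' Reads the minimal tab-separated mutation dialect. The genomic ("maf")
#' dialect requires columns \code{chrom, pos, ref, alt, sample, class}
#' (optional \code{cohort}); the \code{protein} dialect requires
#' \code{gene, protein_pos} (optional \code{sample, cohort, class}), as used
#' for SNP tables already mapped to reference transcripts. Variant classes
#' other than missense/synonymous are retained but tagged \code{"other"};
#' no row is ever silently dropped.
#'
#' @param path path to a TSV file with a header row. Lines starting with
#'   \code{#} are treated as comments.
#' @param dialect \code{"maf"} for genomic coordinates, \code{"protein"} for
#'   protein coordinates.
#' @param columns optional named character vector mapping required column
#'   names to the names actually present in the file (to accept full MAF-like
#'   tables), e.g. \code{c(chrom = "Chromosome")}.
#' @return a data.frame with one row per input row and normalised columns.
#' @export
readMutations <- function(path, dialect = c("maf", "protein"),
                          columns = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    sbStop("siteburden_io_error", "mutation file not found: %s", path)
  }
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character", check.names = FALSE)
  required <- if (dialect == "maf") {
    c("chrom", "pos", "ref", "alt", "sample", "class")
  } else c("gene", "protein_pos")
  if (!is.null(columns)) {
    for (std in names(columns)) {
      if (columns[[std]] %in% names(df)) {
        names(df)[names(df) == columns[[std]]] <- std
      }
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    sbStop("siteburden_format_error", "missing required column(s): %s",
           paste(missing, collapse = ", "))
  }
  posCol <- if (dialect == "maf") "pos" else "protein_pos"
  bad <- which(!grepl("^[0-9]+$", df[[posCol]]))
  if (length(bad)) {
    sbStop("siteburden_format_error",
           "non-numeric %s value %s at line %d", posCol,
           dQuote(df[[posCol]][bad[1]]), bad[1] + 1L)
  }
  df[[posCol]] <- as.integer(df[[posCol]])
  if (any(df[[posCol]] < 1L)) {
    sbStop("siteburden_format_error", "%s must be >= 1", posCol)
  }
  if (dialect == "maf") {
    ok <- df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T")
    if (any(!ok)) {
      sbStop("siteburden_format_error", "invalid allele at line %d",
             which(!ok)[1] + 1L)
    }
    if (any(df$ref == df$alt)) {
      sbStop("siteburden_format_error", "ref == alt at line %d",
             which(df$ref == df$alt)[1] + 1L)
    }
  }
  if (!"cohort" %in% names(df)) df$cohort <- rep(NA_character_, nrow(df))
  if (!"class" %in% names(df)) df$class <- rep("other", nrow(df))
  df$class <- normalizeVarClass(df$class)
  rownames(df) <- NULL
  df
}

normalizeVarClass <- function(x) {
  x <- tolower(x)
  out <- rep("other", length(x))
  out[x %in% c("missense", "missense_mutation")] <- "missense"
  out[x %in% c("synonymous", "silent", "synonymous_variant")] <- "synonymous"
  out
}

#' Read a reference genome FASTA
#'
#' @param path FASTA file path.
#' @return a \code{Biostrings::DNAStringSet}, names truncated at the first
#'   whitespace.
#' @export
readGenome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read transcript (CDS) models
#'
#' Tab-separated with columns \code{gene, isoform, rank, chrom, strand,
#' segments}; \code{segments} is a comma-separated list of 1-based inclusive
#' genomic intervals \code{start-end} in 5'-to-3' transcript order (descending
#' genomic coordinates on the minus strand).
#'
#' @param path TSV file path.
#' @return data.frame with a \code{segments} list-column of 2-column matrices.
#' @export
readTranscriptModels <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  need <- c("gene", "isoform", "rank", "chrom", "strand", "segments")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    sbStop("siteburden_format_error", "missing required column(s): %s",
           paste(missing, collapse = ", "))
  }
  df$rank <- as.integer(df$rank)
  if (!all(df$strand %in% c("+", "-"))) {
    sbStop("siteburden_format_error", "strand must be '+' or '-'")
  }
  df$segments <- lapply(df$segments, parseSegments)
  for (i in seq_len(nrow(df))) {
    seg <- df$segments[[i]]
    len <- sum(seg[, 2] - seg[, 1] + 1L)
    if (len %% 3L != 0L) {
      sbStop("siteburden_format_error",
             "CDS length of %s not divisible by 3", df$isoform[i])
    }
    o <- order(seg[, 1])
    if (any(seg[o, 1][-1] <= seg[o, 2][-nrow(seg)])) {
      sbStop("siteburden_format_error",
             "overlapping CDS segments in %s", df$isoform[i])
    }
  }
  if (anyDuplicated(df[, c("gene", "rank")])) {
    sbStop("siteburden_format_error", "duplicated assembly rank within a gene")
  }
  df
}

parseSegments <- function(s) {
  parts <- strsplit(strsplit(s, ",")[[1]], "-")
  m <- do.call(rbind, lapply(parts, function(p) as.integer(p[1:2])))
  if (any(is.na(m)) || any(m[, 2] < m[, 1])) {
    sbStop("siteburden_format_error", "malformed segment list: %s", s)
  }
  colnames(m) <- c("start", "end")
  m
}

STANDARD_AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L",
  LYS = "K", MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T",
  TRP = "W", TYR = "Y", VAL = "V")

#' Read structure coordinate files and binding annotations
#'
#' Parses PDB-format coordinate files (via \pkg{bio3d}), keeping heavy atoms
#' only (hydrogens dropped, highest-occupancy altloc retained), and a
#' binding-annotation TSV with columns \code{structure_id, chain_id,
#' ligand_id, ligand_chain, ligand_resno, category, binding_residues}
#' (semicolon-separated residue indices against the chain renumbered 1..L).
#'
#' @param pdbPaths character vector of PDB file paths; file base names (minus
#'   extension) are the structure ids.
#' @param biolipPath path of the binding-annotation TSV.
#' @return list with elements \code{chains} (named list of
#'   \linkS4class{StructureChain}, names "structureId_chainId") and
#'   \code{bindingRecords} (list of \linkS4class{BindingRecord}).
#' @export
readStructures <- function(pdbPaths, biolipPath) {
  parsed <- lapply(pdbPaths, parsePdbFile)
  names(parsed) <- vapply(pdbPaths, function(p) {
    sub("\\.(pdb|ent)$", "", basename(p))
  }, "")
  chains <- list()
  for (sid in names(parsed)) {
    for (ch in parsed[[sid]]$chains) {
      chains[[paste(sid, ch@chainId, sep = "_")]] <- ch
    }
  }
  tsv <- read.delim(biolipPath, header = TRUE, sep = "\t",
                    comment.char = "#", colClasses = "character")
  need <- c("structure_id", "chain_id", "ligand_id", "ligand_chain",
            "ligand_resno", "category", "binding_residues")
  missing <- setdiff(need, names(tsv))
  if (length(missing)) {
    sbStop("siteburden_format_error", "missing required column(s): %s",
           paste(missing, collapse = ", "))
  }
  records <- vector("list", nrow(tsv))
  for (i in seq_len(nrow(tsv))) {
    key <- paste(tsv$structure_id[i], tsv$chain_id[i], sep = "_")
    chain <- chains[[key]]
    if (is.null(chain)) {
      sbStop("siteburden_format_error",
             "binding annotation references unknown chain %s", key)
    }
    residues <- as.integer(strsplit(tsv$binding_residues[i], ";")[[1]])
    L <- nchar(chain@sequence)
    out <- residues[residues < 1L | residues > L]
    if (length(out)) {
      sbStop("siteburden_format_error",
             "residue %s not in chain %s (length %d)",
             paste(out, collapse = ","), key, L)
    }
    lig <- ligandFromAtoms(parsed[[tsv$structure_id[i]]]$hetatoms,
                           tsv$ligand_id[i], tsv$ligand_chain[i],
                           as.integer(tsv$ligand_resno[i]),
                           tsv$category[i])
    records[[i]] <- new("BindingRecord", structureId = tsv$structure_id[i],
                        chainId = tsv$chain_id[i], ligand = lig,
                        bindingResidues = sort(unique(residues)))
  }
  list(chains = chains, bindingRecords = records)
}

ligandFromAtoms <- function(het, ligandId, ligandChain, ligandResno,
                            category) {
  sel <- het$resid == ligandId & het$chain == ligandChain &
    het$resno == ligandResno
  if (!any(sel)) {
    sbStop("siteburden_format_error",
           "ligand %s %s/%d has no coordinates", ligandId, ligandChain,
           ligandResno)
  }
  new("LigandRecord", ligandId = ligandId, category = category,
      atoms = as.matrix(het[sel, c("x", "y", "z")]))
}

# Parse one PDB file into protein chains (heavy atoms, re-indexed residues)
# and a table of heavy HETATM records.
parsePdbFile <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- ifelse(is.na(at$elesy) | at$elesy == "",
                 substr(gsub("[0-9 ]", "", at$elety), 1, 1), at$elesy)
  at <- at[!toupper(elem) %in% c("H", "D"), , drop = FALSE]
  # highest-occupancy altloc per (chain, resno, atom name)
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      ix[which.max(occ[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  prot <- at[at$type == "ATOM" & at$resid %in% names(STANDARD_AA3), ,
             drop = FALSE]
  chains <- list()
  for (ch in unique(prot$chain)) {
    sub <- prot[prot$chain == ch, , drop = FALSE]
    resKey <- paste(sub$resno, sub$insert)
    uniq <- unique(resKey)
    newno <- match(resKey, uniq)
    aa <- unname(STANDARD_AA3[sub$resid[match(uniq, resKey)]])
    chains[[ch]] <- new("StructureChain",
      structureId = sub("\\.(pdb|ent)$", "", basename(path)), chainId = ch,
      sequence = paste(aa, collapse = ""),
      atoms = data.frame(resno = as.integer(newno),
                         aa = aa[newno], atom = sub$elety,
                         x = sub$x, y = sub$y, z = sub$z,
                         stringsAsFactors = FALSE))
  }
  het <- at[at$type == "HETATM" & at$resid != "HOH", , drop = FALSE]
  list(chains = chains, hetatoms = het)
}

#' Read homology hits with their pairwise alignments
#'
#' The hits TSV has columns \code{refseq_id, structure_id, chain_id, e_value,
#' pct_identity, coverage, aln_file}; each \code{aln_file} (relative to the
#' TSV's directory) is an aligned FASTA pair: reference sequence first, chain
#' second, equal gapped lengths. Identity and coverage are recomputed from
#' the alignment; file values that disagree trigger a warning and are
#' replaced.
#'
#' @param path hits TSV path.
#' @return list of \linkS4class{HomologyHit}.
#' @export
readHomologyHits <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  need <- c("refseq_id", "structure_id", "chain_id", "e_value",
            "pct_identity", "coverage", "aln_file")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    sbStop("siteburden_format_error", "missing required column(s): %s",
           paste(missing, collapse = ", "))
  }
  base <- dirname(path)
  lapply(seq_len(nrow(df)), function(i) {
    aln <- Biostrings::readBStringSet(file.path(base, df$aln_file[i]))
    if (length(aln) != 2L) {
      sbStop("siteburden_format_error",
             "alignment %s must contain exactly 2 sequences", df$aln_file[i])
    }
    cols <- alignmentColumns(as.character(aln[[1]]), as.character(aln[[2]]))
    st <- alignmentStats(cols)
    claimed <- c(as.numeric(df$pct_identity[i]), as.numeric(df$coverage[i]))
    if (any(abs(claimed - c(st$identity, st$coverage)) > 1e-6)) {
      warning(sprintf(
        "hit %s->%s_%s: identity/coverage recomputed from alignment (%0.4f/%0.4f)",
        df$refseq_id[i], df$structure_id[i], df$chain_id[i],
        st$identity, st$coverage), call. = FALSE)
    }
    new("HomologyHit", refseqId = df$refseq_id[i],
        structureId = df$structure_id[i], chainId = df$chain_id[i],
        eValue = as.numeric(df$e_value[i]), pctIdentity = st$identity,
        structureCoverage = st$coverage, alignment = cols)
  })
}

SITE_RESULT_COLUMNS <- c("gene", "site_id", "category", "n_binding_residues",
  "mutated_binding_positions", "m", "s_b", "p_empirical", "fdr", "cohort")

#' Write / read binding-site test results
#'
#' Writes a TSV with stable column order (\code{gene, site_id, category,
#' n_binding_residues, mutated_binding_positions, m, s_b, p_empirical, fdr,
#' cohort}) and deterministic row order (gene, then site id). Optional
#' provenance lines are written as leading \code{#} comments.
#'
#' @param results data.frame of site test results.
#' @param path output TSV path.
#' @param provenance optional character vector of comment lines.
#' @export
writeSiteResults <- function(results, path, provenance = NULL) {
  if (nrow(results)) {
    missing <- setdiff(SITE_RESULT_COLUMNS, names(results))
    if (length(missing)) {
      sbStop("siteburden_format_error", "results missing column(s): %s",
             paste(missing, collapse = ", "))
    }
    results <- results[order(results$gene, results$site_id),
                       SITE_RESULT_COLUMNS, drop = FALSE]
  } else {
    results <- as.data.frame(setNames(
      rep(list(character(0)), length(SITE_RESULT_COLUMNS)),
      SITE_RESULT_COLUMNS))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  writeLines(paste(SITE_RESULT_COLUMNS, collapse = "\t"), con)
  if (nrow(results)) {
    num <- vapply(results, is.numeric, TRUE)
    results[num] <- lapply(results[num], function(x) {
      formatC(x, digits = 15, format = "g")
    })
    writeLines(do.call(paste, c(unname(results), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname writeSiteResults
#' @export
readSiteResults <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  for (col in c("n_binding_residues", "mutated_binding_positions", "m")) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("s_b", "p_empirical", "fdr")) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Read a gene list (one symbol per line)
#'
#' @param path text file path; blank lines and \code{#} comments ignored.
#' @return character vector of unique gene symbols.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read cohort metadata (cohort label + sample count)
#'
#' @param path TSV with columns \code{cohort, samples}.
#' @return data.frame with integer \code{samples}.
#' @export
readCohortTable <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  missing <- setdiff(c("cohort", "samples"), names(df))
  if (length(missing)) {
    sbStop("siteburden_format_error", "missing required column(s): %s",
           paste(missing, collapse = ", "))
  }
  df$samples <- as.integer(df$samples)
  df
}

# --- writers used by the fixture generator and pipeline stages -------------

writeTsv <- function(df, path, listCols = NULL) {
  for (col in listCols) {
    df[[col]] <- vapply(df[[col]], function(m) {
      paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ",")
    }, "")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Minimal fixed-width PDB writer for synthetic structures.
writePdbFile <- function(path, records) {
  lines <- sprintf(
    "%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    records$type, seq_len(nrow(records)), records$atom, records$resid,
    records$chain, records$resno, records$x, records$y, records$z,
    1, 0, records$elem)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
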
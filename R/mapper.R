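complementBase <- function(x) chartr("ACGT", "TGCA", x)

# Spliced CDS (5'->3' transcript orientation) as a character string.
# Segments are taken in the stored transcript order; minus-strand segments
# are reverse-complemented.
splicedCds <- function(tx, genome) {
  chromSeq <- genome[[tx$chrom]]
  pieces <- apply(tx$segments[[1]], 1, function(seg) {
    s <- Biostrings::subseq(chromSeq, seg[1], seg[2])
    if (tx$strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  })
  paste(pieces, collapse = "")
}

translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# 1-based offset of genomic position pos within the spliced CDS, or NA when
# the position falls outside every CDS segment.
cdsOffsetOf <- function(tx, pos) {
  seg <- tx$segments[[1]]
  lens <- seg[, 2] - seg[, 1] + 1L
  before <- c(0L, cumsum(lens))[seq_len(nrow(seg))]
  for (i in seq_len(nrow(seg))) {
    if (pos >= seg[i, 1] && pos <= seg[i, 2]) {
      within <- if (tx$strand == "+") pos - seg[i, 1] + 1L
                else seg[i, 2] - pos + 1L
      return(before[i] + within)
    }
  }
  NA_integer_
}

#' Map one genomic mutation onto one transcript isoform
#'
#' Locates the mutated base within the isoform's spliced CDS (strand-aware),
#' translates the reference and mutated codon with the standard genetic code,
#' and returns the mutation in protein coordinates. The variant class is
#' derived from the codon translation: \code{synonymous} when the amino acid
#' is unchanged, \code{missense} when it changes to another amino acid, and
#' \code{other} when a stop codon is created.
#'
#' @param mut one-row data.frame (or list) with \code{chrom, pos, ref, alt,
#'   sample, cohort}.
#' @param tx one-row transcript model data.frame (from
#'   \code{\link{readTranscriptModels}}).
#' @param genome a \code{DNAStringSet} (from \code{\link{readGenome}}).
#' @param cds optional precomputed spliced CDS string for \code{tx}.
#' @return a list with \code{gene, isoform, protein_pos, ref_aa, alt_aa,
#'   sample, cohort, class}, or \code{NULL} when the position does not fall
#'   in the isoform's CDS. A reference-allele disagreement with the genome
#'   raises a \code{siteburden_refmismatch_error} carrying both bases.
#' @export
mapMutationToIsoform <- function(mut, tx, genome, cds = NULL) {
  if (mut$chrom != tx$chrom) return(NULL)
  offset <- cdsOffsetOf(tx, mut$pos)
  if (is.na(offset)) return(NULL)
  genomeBase <- as.character(
    Biostrings::subseq(genome[[tx$chrom]], mut$pos, mut$pos))
  if (genomeBase != mut$ref) {
    sbStop("siteburden_refmismatch_error",
           "reference mismatch at %s:%d (mutation says %s, genome says %s)",
           mut$chrom, mut$pos, mut$ref, genomeBase)
  }
  if (is.null(cds)) cds <- splicedCds(tx, genome)
  codonIdx <- (offset - 1L) %/% 3L + 1L
  within <- offset - 3L * (codonIdx - 1L)
  refCodon <- substr(cds, 3L * codonIdx - 2L, 3L * codonIdx)
  altBase <- if (tx$strand == "-") complementBase(mut$alt) else mut$alt
  altCodon <- refCodon
  substr(altCodon, within, within) <- altBase
  refAA <- translateCodon(refCodon)
  altAA <- translateCodon(altCodon)
  cls <- if (refAA == "*" || altAA == "*") "other"
         else if (refAA == altAA) "synonymous" else "missense"
  list(gene = tx$gene, isoform = tx$isoform,
       protein_pos = as.integer(unname(codonIdx)),
       ref_aa = refAA, alt_aa = altAA,
       sample = mut$sample, cohort = mut$cohort, class = cls)
}

#' Choose the reference isoform of a gene
#'
#' The isoform mapping the largest number of distinct mutated protein
#' positions wins; ties are broken by the lowest assembly rank (the first
#' isoform reported in the assembly).
#'
#' @param counts named integer vector: distinct mapped mutated positions per
#'   isoform.
#' @param ranks named integer vector of assembly ranks (same names).
#' @return name of the chosen isoform.
#' @export
selectIsoform <- function(counts, ranks) {
  stopifnot(length(counts) >= 1L, all(names(counts) %in% names(ranks)))
  best <- names(counts)[counts == max(counts)]
  best[which.min(ranks[best])]
}

#' Build the reference protein set and map all mutations onto it
#'
#' Maps every mutation onto every isoform of the gene(s) covering its locus,
#' selects one reference isoform per gene (the one mapping the most distinct
#' mutated positions, pooled over cohorts; ties to the lowest assembly rank),
#' and reports each input mutation as either mapped on the chosen isoform or
#' unmapped with a reason. Counts are conserved: every input row appears in
#' exactly one of the two outputs.
#'
#' @param mutations data.frame from \code{\link{readMutations}} (genomic
#'   dialect).
#' @param transcripts data.frame from \code{\link{readTranscriptModels}}.
#' @param genome \code{DNAStringSet}.
#' @return list with \code{mapped} (protein mutations: gene, isoform,
#'   protein_pos, ref_aa, alt_aa, sample, cohort, class), \code{unmapped}
#'   (input rows + reason), \code{isoformMappings} (per gene: chosen isoform
#'   and per-isoform candidate counts), and \code{refseqs} (named character
#'   vector of chosen-isoform protein sequences).
#' @export
buildReferenceSet <- function(mutations, transcripts, genome) {
  txCds <- vapply(seq_len(nrow(transcripts)), function(i) {
    splicedCds(transcripts[i, ], genome)
  }, "")
  # candidate (mutation, isoform) protein calls; each entry is
  # list(mutRow, ok, call-or-message)
  calls <- vector("list", nrow(transcripts))
  for (t in seq_len(nrow(transcripts))) {
    tx <- transcripts[t, ]
    seg <- tx$segments[[1]]
    res <- list()
    for (i in which(mutations$chrom == tx$chrom &
                    mutations$pos >= min(seg) & mutations$pos <= max(seg))) {
      entry <- tryCatch({
        pm <- mapMutationToIsoform(mutations[i, ], tx, genome, cds = txCds[t])
        if (is.null(pm)) NULL else list(mutRow = i, ok = TRUE, call = pm)
      }, siteburden_refmismatch_error = function(e) {
        list(mutRow = i, ok = FALSE, msg = conditionMessage(e))
      })
      if (!is.null(entry)) res[[length(res) + 1L]] <- entry
    }
    calls[[t]] <- res
  }

  mapped <- list()
  unmappedReason <- rep(NA_character_, nrow(mutations))
  mappedRows <- rep(FALSE, nrow(mutations))
  isoMapList <- list()
  refseqs <- character(0)

  for (g in unique(transcripts$gene)) {
    tIdx <- which(transcripts$gene == g)
    tIdx <- tIdx[order(transcripts$rank[tIdx])]
    counts <- integer(0)
    ranks <- integer(0)
    for (t in tIdx) {
      good <- Filter(function(x) x$ok &&
                       x$call$class %in% c("missense", "synonymous"),
                     calls[[t]])
      counts[transcripts$isoform[t]] <-
        length(unique(vapply(good, function(x) x$call$protein_pos, 1L)))
      ranks[transcripts$isoform[t]] <- transcripts$rank[t]
    }
    chosen <- selectIsoform(counts, ranks)
    tChosen <- tIdx[transcripts$isoform[tIdx] == chosen]
    refseqs[g] <- translateCdsToProtein(txCds[tChosen])
    for (x in calls[[tChosen]]) {
      if (!x$ok) {
        unmappedReason[x$mutRow] <- x$msg
        next
      }
      mapped[[length(mapped) + 1L]] <- x$call
      mappedRows[x$mutRow] <- TRUE
    }
    isoMapList[[g]] <- data.frame(
      gene = g, chosen_isoform = chosen,
      mapped_positions = counts[[chosen]],
      candidate_counts = paste(sprintf("%s:%d", names(counts), counts),
                               collapse = ";"),
      stringsAsFactors = FALSE)
  }

  # rows that mapped only on a non-chosen isoform
  for (t in seq_len(nrow(transcripts))) {
    for (x in calls[[t]]) {
      if (x$ok && !mappedRows[x$mutRow] && is.na(unmappedReason[x$mutRow])) {
        unmappedReason[x$mutRow] <- "not in CDS of chosen isoform"
      }
    }
  }
  unmappedReason[!mappedRows & is.na(unmappedReason)] <- "not in CDS"

  mappedDf <- if (length(mapped)) {
    data.frame(
      gene = vapply(mapped, `[[`, "", "gene"),
      isoform = vapply(mapped, `[[`, "", "isoform"),
      protein_pos = vapply(mapped, `[[`, 1L, "protein_pos"),
      ref_aa = vapply(mapped, `[[`, "", "ref_aa"),
      alt_aa = vapply(mapped, `[[`, "", "alt_aa"),
      sample = vapply(mapped, `[[`, "", "sample"),
      cohort = vapply(mapped, `[[`, "", "cohort"),
      class = vapply(mapped, `[[`, "", "class"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), isoform = character(0),
               protein_pos = integer(0), ref_aa = character(0),
               alt_aa = character(0), sample = character(0),
               cohort = character(0), class = character(0))
  }
  unmappedIdx <- which(!mappedRows)
  unmappedDf <- cbind(mutations[unmappedIdx, , drop = FALSE],
                      reason = unmappedReason[unmappedIdx])
  rownames(unmappedDf) <- NULL
  list(mapped = mappedDf, unmapped = unmappedDf,
       isoformMappings = do.call(rbind, unname(isoMapList)),
       refseqs = refseqs)
}

# Translate a CDS string to protein, dropping a trailing stop codon if
# present; an internal stop is a format error.
translateCdsToProtein <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("\\*", aa)) {
    sbStop("siteburden_format_error", "internal stop codon in CDS")
  }
  aa
}
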
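#' Assemble cohort-level burden counts
#'
#' Computes the quadruple used by the cohort-level hypergeometric test:
#' N = positions with structural information, K = binding positions,
#' n = structural positions hit by at least one variant of the class under
#' test, k = binding positions hit. Positions count once regardless of
#' recurrence, pooled over all reference sequences. With \code{category}
#' set, K and k are restricted to that ligand category while N and n stay
#' global (each category is tested against the same structural background).
#'
#' @param siteSet a \linkS4class{BindingSiteSet}.
#' @param variants data.frame of protein-coordinate variants with columns
#'   \code{gene} and \code{protein_pos} (pre-filtered to one variant class).
#' @param category optional ligand category ("NUC"/"PEP"/"SMI").
#' @return list with integer elements \code{N, K, n, k}.
#' @export
assembleCounts <- function(siteSet, variants, category = NULL) {
  sp <- structuralPositions(siteSet)
  N <- sum(lengths(sp))
  keep <- bindingSites(siteSet)
  if (!is.null(category)) {
    keep <- Filter(function(s) s@category == category, keep)
  }
  bindingByRef <- lapply(split(keep, vapply(keep, slot, "", "refseqId")),
                         function(ss) {
                           sort(unique(unlist(lapply(ss, slot, "positions"))))
                         })
  K <- sum(lengths(bindingByRef))
  n <- 0L
  k <- 0L
  for (r in names(sp)) {
    hit <- unique(variants$protein_pos[variants$gene == r])
    hitStruct <- intersect(hit, sp[[r]])
    n <- n + length(hitStruct)
    k <- k + length(intersect(hitStruct, bindingByRef[[r]]))
  }
  counts <- list(N = as.integer(N), K = as.integer(K),
                 n = as.integer(n), k = as.integer(k))
  validateCounts(counts)
  counts
}

validateCounts <- function(counts) {
  with(counts, {
    if (K > N || n > N || k > min(K, n)) {
      sbStop("siteburden_usage_error",
             "invalid counts: N=%d K=%d n=%d k=%d", N, K, n, k)
    }
  })
  invisible(counts)
}

#' Exact hypergeometric tail probability for the burden counts
#'
#' Under the null that binding positions are hit with the same probability
#' as any other structural position, the number of binding positions hit is
#' hypergeometric with parameters (N, K, n). The upper tail P(X >= k) is
#' used for cancer missense mutations, the lower tail P(X <= k) for SNPs.
#'
#' @param counts list with \code{N, K, n, k} (see
#'   \code{\link{assembleCounts}}).
#' @param tail \code{"upper"} or \code{"lower"}.
#' @return the exact tail probability.
#' @export
hypergeomTail <- function(counts, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  validateCounts(counts)
  with(counts, {
    if (tail == "upper") phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    else phyper(k, K, N - K, n)
  })
}

#' Frequency-aware binomial burden test
#'
#' The companion test counting mutation events with their frequency: upper
#' tail P(X >= bindingEvents) of a binomial with size totalEvents and
#' success probability q, the fraction of structural residues that are
#' binding residues.
#'
#' @param bindingEvents events hitting binding residues.
#' @param totalEvents all events at structural residues.
#' @param q fraction of structural residues that are binding residues.
#' @return the exact upper-tail probability.
#' @export
binomialFrequencyTest <- function(bindingEvents, totalEvents, q) {
  stopifnot(q >= 0, q <= 1, bindingEvents >= 0,
            bindingEvents <= totalEvents)
  pbinom(bindingEvents - 1, totalEvents, q, lower.tail = FALSE)
}

#' Enrichment ratio of a positive gene set among selected items
#'
#' @param selPositive,selTotal positives among the selected items.
#' @param bgPositive,bgTotal positives among the background items.
#' @return (selPositive/selTotal) / (bgPositive/bgTotal); NA when a
#'   denominator is 0.
#' @export
enrichmentRatio <- function(selPositive, selTotal, bgPositive, bgTotal) {
  if (selTotal == 0 || bgTotal == 0 || bgPositive == 0) return(NA_real_)
  (selPositive / selTotal) / (bgPositive / bgTotal)
}

#' Known-cancer-gene enrichment as a function of the p-value threshold
#'
#' For each threshold, selects the sites (or genes) with a permutation
#' p-value at or below it and computes the enrichment of curated cancer
#' genes (CCGs) among the selection relative to the background of all sites
#' (genes) with at least one mutated binding position.
#'
#' @param siteResults data.frame from \code{\link{testBindingSites}} (or
#'   read back by \code{\link{readSiteResults}}).
#' @param ccgGenes character vector of curated cancer gene symbols.
#' @param thresholds numeric p-value thresholds; default = the 1%, 2.5%,
#'   5%, 10% and 25% quantiles of the observed p-value distribution.
#' @param unit counting unit of the numerator/denominator: \code{"site"}
#'   (default) or \code{"gene"}.
#' @return data.frame with one row per threshold: \code{p_threshold,
#'   selected, ccg_in_selected, background_total, ccg_in_background,
#'   enrichment_ratio}.
#' @export
ccgEnrichmentCurve <- function(siteResults, ccgGenes, thresholds = NULL,
                               unit = c("site", "gene")) {
  unit <- match.arg(unit)
  bg <- siteResults[siteResults$mutated_binding_positions >= 1L, ,
                    drop = FALSE]
  if (is.null(thresholds)) {
    thresholds <- unname(quantile(bg$p_empirical,
                                  c(0.01, 0.025, 0.05, 0.10, 0.25)))
  }
  isCcg <- bg$gene %in% ccgGenes
  if (unit == "gene") {
    bgTotal <- length(unique(bg$gene))
    bgPos <- length(unique(bg$gene[isCcg]))
  } else {
    bgTotal <- nrow(bg)
    bgPos <- sum(isCcg)
  }
  rows <- lapply(thresholds, function(thr) {
    sel <- bg[bg$p_empirical <= thr, , drop = FALSE]
    if (unit == "gene") {
      selTotal <- length(unique(sel$gene))
      selPos <- length(unique(sel$gene[sel$gene %in% ccgGenes]))
    } else {
      selTotal <- nrow(sel)
      selPos <- sum(sel$gene %in% ccgGenes)
    }
    data.frame(p_threshold = thr, selected = selTotal,
               ccg_in_selected = selPos, background_total = bgTotal,
               ccg_in_background = bgPos,
               enrichment_ratio = enrichmentRatio(selPos, selTotal,
                                                  bgPos, bgTotal))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
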
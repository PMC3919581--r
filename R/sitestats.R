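#' Observed burden score of a binding site
#'
#' s_b is the sum, over the site's mutated residues, of the residue's binding
#' score b_i multiplied by the number of distinct samples with a missense
#' mutation at that residue (repeated records of the same sample at the same
#' residue count once).
#'
#' @param site a \linkS4class{MappedBindingSite}.
#' @param mutations protein mutation data.frame (columns \code{gene,
#'   protein_pos, sample, class}); only missense rows on the site's refseq
#'   are used.
#' @return the observed site score s_b.
#' @export
siteScore <- function(site, mutations) {
  mu <- mutations[mutations$gene == site@refseqId &
                    mutations$class == "missense" &
                    mutations$protein_pos %in% site@positions, , drop = FALSE]
  if (!nrow(mu)) return(0)
  perPos <- tapply(mu$sample, mu$protein_pos,
                   function(s) length(unique(s)))
  sum(site@bindingScores[names(perPos)] * as.integer(perPos))
}

#' Permutation test of a site's mutation burden
#'
#' Each replicate draws \code{m} positions uniformly with replacement from
#' the refseq's structural positions and scores the draw as the sum of the
#' binding scores of the drawn positions (0 off-site). The empirical p-value
#' is the fraction of replicates scoring at least the observed s_b (ties
#' count as extreme; \code{tieConvention = "gt"} uses a strict comparison).
#' A zero replicate count is floored at 1/R so p stays in (0, 1]; m = 0
#' returns p = 1.
#'
#' @param scores named numeric vector of binding scores b over the site's
#'   positions.
#' @param structuralPositions integer vector: all positions of the refseq
#'   with structural information (sampling universe; must contain the site).
#' @param m number of mutation events at structural positions.
#' @param sObs observed site score.
#' @param replicates number of replicates R (default 1e5).
#' @param seed integer seed for this test.
#' @param tieConvention \code{"ge"} (default) or \code{"gt"}.
#' @return empirical p-value in (0, 1].
#' @export
permutationTest <- function(scores, structuralPositions, m, sObs,
                            replicates = 1e5, seed = 1L,
                            tieConvention = c("ge", "gt")) {
  tieConvention <- match.arg(tieConvention)
  stopifnot(replicates >= 1, m >= 0)
  if (m == 0) return(1)
  if (!length(structuralPositions)) {
    sbStop("siteburden_usage_error",
           "no structural positions but m = %d", m)
  }
  if (!all(as.integer(names(scores)) %in% structuralPositions)) {
    sbStop("siteburden_usage_error",
           "site positions outside structural positions")
  }
  bvec <- numeric(length(structuralPositions))
  bvec[match(as.integer(names(scores)), structuralPositions)] <- scores
  replicates <- as.integer(replicates)
  withSeed(seed, {
    count <- 0
    chunk <- max(1L, min(replicates, as.integer(2e7 / m)))
    done <- 0L
    eps <- 1e-9
    while (done < replicates) {
      nrep <- min(chunk, replicates - done)
      draws <- bvec[sample.int(length(bvec), m * nrep, replace = TRUE)]
      repScores <- .colSums(draws, m, nrep)
      count <- count + if (tieConvention == "ge") {
        sum(repScores >= sObs - eps)
      } else {
        sum(repScores > sObs + eps)
      }
      done <- done + nrep
    }
    max(count, 1L) / replicates
  })
}

# evaluate expr under a local RNG seed, restoring global RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up adjustment; input order is preserved on return.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted FDR values in [0, 1].
#' @export
bhFdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    sbStop("siteburden_usage_error", "p-values must lie in [0,1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Test every binding site of a run for mutation enrichment
#'
#' For each reference sequence: m is the number of missense mutation events
#' at its structural positions (with per-sample multiplicity by default;
#' \code{multiplicityMode = "positions"} counts distinct mutated positions
#' instead); each site's observed s_b uses distinct samples per residue.
#' Per-site p-values come from \code{\link{permutationTest}} with a child
#' seed derived from (seed, refseq, site), so results do not depend on
#' iteration order; FDRs are computed across all sites of the run.
#'
#' @param siteSet a \linkS4class{BindingSiteSet}.
#' @param mutations protein mutation data.frame (\code{gene, protein_pos,
#'   sample, cohort, class}).
#' @param replicates permutation replicates R (default 1e5).
#' @param seed master seed.
#' @param cohort optional cohort label: restrict to that cohort's mutations;
#'   NULL pools all cohorts (aggregate analysis).
#' @param tieConvention,multiplicityMode see Details.
#' @return data.frame with columns \code{gene, site_id, category,
#'   n_binding_residues, mutated_binding_positions, m, s_b, p_empirical,
#'   fdr, cohort}.
#' @export
testBindingSites <- function(siteSet, mutations, replicates = 1e5,
                             seed = 1L, cohort = NULL,
                             tieConvention = c("ge", "gt"),
                             multiplicityMode = c("events", "positions")) {
  tieConvention <- match.arg(tieConvention)
  multiplicityMode <- match.arg(multiplicityMode)
  cohortLabel <- if (is.null(cohort)) "ALL" else cohort
  mu <- mutations[mutations$class == "missense", , drop = FALSE]
  if (!is.null(cohort)) mu <- mu[mu$cohort == cohort, , drop = FALSE]

  sites <- bindingSites(siteSet)
  if (!length(sites)) {
    return(data.frame(gene = character(0), site_id = character(0),
                      category = character(0),
                      n_binding_residues = integer(0),
                      mutated_binding_positions = integer(0),
                      m = integer(0), s_b = numeric(0),
                      p_empirical = numeric(0), fdr = numeric(0),
                      cohort = character(0)))
  }
  rows <- lapply(sites, function(site) {
    sp <- structuralPositions(siteSet, site@refseqId)
    muRef <- mu[mu$gene == site@refseqId & mu$protein_pos %in% sp, ,
                drop = FALSE]
    m <- if (multiplicityMode == "events") nrow(muRef)
         else length(unique(muRef$protein_pos))
    sObs <- siteScore(site, mu)
    p <- permutationTest(site@bindingScores, sp, m, sObs,
                         replicates = replicates,
                         seed = deriveSeed(seed, site@refseqId, site@siteId),
                         tieConvention = tieConvention)
    data.frame(gene = site@refseqId, site_id = site@siteId,
               category = site@category,
               n_binding_residues = length(site@positions),
               mutated_binding_positions = length(
                 intersect(unique(muRef$protein_pos), site@positions)),
               m = m, s_b = sObs, p_empirical = p, fdr = NA_real_,
               cohort = cohortLabel, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bhFdr(res$p_empirical)
  res <- res[order(res$gene, res$site_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
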
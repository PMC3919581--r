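#' Filter homology hits into accepted structural matches
#'
#' A hit is accepted iff E-value < 1e-6 AND sequence identity > 0.60 AND
#' coverage of the matching structure chain > 0.80, all strict inequalities.
#' Rejected hits are retained with the first failed filter as the reason.
#'
#' @param hits list of \linkS4class{HomologyHit}.
#' @param eValueMax,identityMin,coverageMin filter thresholds.
#' @return list of \linkS4class{StructuralMatch}.
#' @export
filterHits <- function(hits, eValueMax = 1e-6, identityMin = 0.60,
                       coverageMin = 0.80) {
  lapply(hits, function(h) {
    reason <- if (!(h@eValue < eValueMax)) {
      sprintf("e_value %.3g not < %.3g", h@eValue, eValueMax)
    } else if (!(h@pctIdentity > identityMin)) {
      sprintf("identity %.3f not > %.2f", h@pctIdentity, identityMin)
    } else if (!(h@structureCoverage > coverageMin)) {
      sprintf("coverage %.3f not > %.2f", h@structureCoverage, coverageMin)
    } else "accepted"
    new("StructuralMatch", hit = h, accepted = reason == "accepted",
        reason = reason)
  })
}

#' Transfer the binding residues of one record onto a reference sequence
#'
#' Chain binding residues are mapped through the pairwise alignment onto
#' reference-sequence positions. The transfer succeeds only if the fraction
#' of binding residues whose aligned reference amino acid is identical
#' exceeds the gate (default 0.90, strict); a binding residue aligned to a
#' gap counts as non-identical and contributes no position.
#'
#' @param match an accepted \linkS4class{StructuralMatch}.
#' @param record a \linkS4class{BindingRecord} on the matched chain.
#' @param bindingIdentityMin identity gate over binding residues.
#' @return list with \code{transferred} (logical), \code{bindingIdentity},
#'   \code{positions} (refseq positions of aligned binding residues) and
#'   \code{chainMap} (named integer: refseq position -> chain residue).
#' @export
transferBindingSite <- function(match, record, bindingIdentityMin = 0.90) {
  stopifnot(is(match, "StructuralMatch"))
  if (!match@accepted) {
    sbStop("siteburden_usage_error",
           "transferBindingSite requires an accepted match")
  }
  al <- match@hit@alignment
  B <- record@bindingResidues
  idx <- match(B, al$chainPos)          # column of each binding residue
  aligned <- !is.na(idx) & !is.na(al$refPos[idx])
  identical <- aligned &
    al$refAA[replace(idx, is.na(idx), 1L)] ==
    al$chainAA[replace(idx, is.na(idx), 1L)]
  identity <- sum(identical) / length(B)
  positions <- al$refPos[idx[aligned]]
  list(transferred = identity > bindingIdentityMin,
       bindingIdentity = identity,
       positions = as.integer(positions),
       chainMap = setNames(B[aligned], positions))
}

#' Merge overlapping binding sites on one reference sequence
#'
#' Sites of the same ligand category sharing at least one residue are merged
#' (transitive closure of the overlap relation); disjoint sites and sites of
#' different categories stay separate. The result is independent of input
#' order.
#'
#' @param sites list of lists with elements \code{category} and
#'   \code{positions} (integer vector).
#' @return list of merged sites: \code{category}, \code{positions} (sorted),
#'   \code{members} (indices of the input sites merged in).
#' @export
mergeSites <- function(sites) {
  if (!length(sites)) return(list())
  out <- list()
  for (cat in sort(unique(vapply(sites, `[[`, "", "category")))) {
    idx <- which(vapply(sites, `[[`, "", "category") == cat)
    parent <- seq_along(idx)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        if (length(intersect(sites[[idx[a]]]$positions,
                             sites[[idx[b]]]$positions))) {
          parent[find(a)] <- find(b)
        }
      }
    }
    roots <- vapply(seq_along(idx), find, 1L)
    for (r in unique(roots)) {
      members <- idx[roots == r]
      pos <- sort(unique(unlist(lapply(sites[members], `[[`, "positions"))))
      out[[length(out) + 1L]] <- list(category = cat, positions = pos,
                                      members = sort(members))
    }
  }
  # deterministic order: category, then first position
  ord <- order(vapply(out, `[[`, "", "category"),
               vapply(out, function(s) as.numeric(s$positions[1]), 1))
  out[ord]
}

#' Heavy-atom ligand contact profile of chain residues
#'
#' For each requested residue, counts its heavy atoms and the subset lying
#' within the contact radius (default 4.0 Angstrom, inclusive) of any ligand
#' heavy atom.
#'
#' @param chain a \linkS4class{StructureChain}.
#' @param ligandAtoms numeric matrix (n x 3) of ligand heavy-atom
#'   coordinates, or a \linkS4class{LigandRecord}.
#' @param residues integer vector of chain residue indices.
#' @param radius contact radius in Angstrom (inclusive).
#' @return data.frame with \code{resno, nAtoms, nContact, fraction};
#'   residues without coordinates are skipped with a warning.
#' @export
contactProfile <- function(chain, ligandAtoms, residues,
                           radius = CONTACT_RADIUS) {
  if (is(ligandAtoms, "LigandRecord")) ligandAtoms <- ligandAtoms@atoms
  rows <- lapply(residues, function(r) {
    a <- chain@atoms[chain@atoms$resno == r, c("x", "y", "z"), drop = FALSE]
    if (!nrow(a)) {
      warning(sprintf("residue %d of %s_%s has no coordinates; skipped",
                      r, chain@structureId, chain@chainId), call. = FALSE)
      return(NULL)
    }
    m <- as.matrix(a)
    d2 <- outer(rowSums(m^2), rowSums(ligandAtoms^2), "+") -
      2 * tcrossprod(m, ligandAtoms)
    nC <- sum(sqrt(pmax(0, apply(d2, 1, min))) <= radius + 1e-9)
    data.frame(resno = r, nAtoms = nrow(m), nContact = nC,
               fraction = nC / nrow(m))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Per-residue binding score
#'
#' The binding score b of a reference position is the mean, over the
#' structures that cover and resolve the residue, of the fraction of the
#' residue's heavy atoms within the contact radius of any ligand atom.
#' Always in [0, 1]; an annotated binding residue with no ligand contact in
#' any covering structure scores 0.
#'
#' @param fractions numeric vector of per-structure contact fractions.
#' @return the binding score (mean fraction).
#' @export
bindingScore <- function(fractions) {
  if (!length(fractions)) {
    sbStop("siteburden_usage_error", "empty contact profile")
  }
  if (any(fractions < 0 | fractions > 1)) {
    sbStop("siteburden_usage_error", "contact fractions outside [0,1]")
  }
  mean(fractions)
}

#' Annotate reference sequences with merged, scored binding sites
#'
#' Runs the full transfer stage: keeps accepted matches, transfers every
#' binding record passing the binding-residue identity gate, merges
#' overlapping sites within each ligand category, and assigns each site
#' position its binding score (mean heavy-atom contact fraction over the
#' accepted structures covering and resolving the position, computed against
#' the ligand atoms of the site's category in each structure). Also records,
#' per reference sequence, the set of structural positions (covered by at
#' least one accepted match) used by the downstream statistics.
#'
#' @param refseqs named character vector of reference protein sequences.
#' @param matches list of \linkS4class{StructuralMatch} (from
#'   \code{\link{filterHits}}).
#' @param bindingRecords list of \linkS4class{BindingRecord}.
#' @param chains named list of \linkS4class{StructureChain}
#'   ("structureId_chainId").
#' @param bindingIdentityMin transfer gate (default 0.90).
#' @param radius contact radius in Angstrom.
#' @return a \linkS4class{BindingSiteSet}.
#' @export
annotateReference <- function(refseqs, matches, bindingRecords, chains,
                              bindingIdentityMin = 0.90,
                              radius = CONTACT_RADIUS) {
  recKey <- vapply(bindingRecords, function(r) {
    paste(r@structureId, r@chainId, sep = "_")
  }, "")
  sites <- list()
  structural <- list()
  lengths <- setNames(nchar(refseqs), names(refseqs))

  for (r in names(refseqs)) {
    acc <- Filter(function(m) m@accepted && m@hit@refseqId == r, matches)
    if (!length(acc)) next
    cov <- sort(unique(unlist(lapply(acc, function(m) {
      al <- m@hit@alignment
      al$refPos[!is.na(al$refPos) & !is.na(al$chainPos)]
    }))))
    structural[[r]] <- as.integer(cov)

    raw <- list()
    for (m in acc) {
      key <- paste(m@hit@structureId, m@hit@chainId, sep = "_")
      for (rec in bindingRecords[recKey == key]) {
        tr <- transferBindingSite(m, rec, bindingIdentityMin)
        if (tr$transferred && length(tr$positions)) {
          raw[[length(raw) + 1L]] <- list(category = rec@ligand@category,
                                          positions = tr$positions)
        }
      }
    }
    if (!length(raw)) next
    merged <- mergeSites(raw)

    catCount <- integer(0)
    for (ms in merged) {
      scores <- vapply(ms$positions, function(i) {
        fractions <- numeric(0)
        srcs <- character(0)
        for (m in acc) {
          al <- m@hit@alignment
          col <- which(!is.na(al$refPos) & al$refPos == i &
                         !is.na(al$chainPos))
          if (!length(col)) next
          key <- paste(m@hit@structureId, m@hit@chainId, sep = "_")
          chain <- chains[[key]]
          resAtoms <- chain@atoms[chain@atoms$resno == al$chainPos[col],
                                  c("x", "y", "z"), drop = FALSE]
          if (!nrow(resAtoms)) next   # unresolved residue: excluded from mean
          lig <- do.call(rbind, lapply(
            bindingRecords[recKey == key &
              vapply(bindingRecords, function(x) x@ligand@category, "") ==
              ms$category],
            function(x) x@ligand@atoms))
          fractions <- c(fractions, if (is.null(lig)) 0 else {
            prof <- contactProfile(chain, lig, al$chainPos[col], radius)
            prof$fraction
          })
        }
        if (!length(fractions)) 0 else bindingScore(fractions)
      }, 1)
      catCount[ms$category] <- (if (ms$category %in% names(catCount))
        catCount[[ms$category]] else 0L) + 1L
      srcIds <- sort(unique(unlist(lapply(acc, function(m) {
        paste(m@hit@structureId, m@hit@chainId, sep = "_")
      }))))
      sites[[length(sites) + 1L]] <- new("MappedBindingSite",
        refseqId = r,
        siteId = sprintf("%s_%d", ms$category, catCount[[ms$category]]),
        category = ms$category, positions = as.integer(ms$positions),
        bindingScores = setNames(scores, ms$positions),
        sourceStructures = srcIds)
    }
  }
  new("BindingSiteSet", sites = sites, structuralPositions = structural,
      refseqLengths = lengths)
}

#' Minimum heavy-atom distance between two residues of a structure
#'
#' Reads a PDB coordinate file, drops hydrogens, and returns the minimum
#' Euclidean distance between the heavy atoms of two residues identified by
#' chain and author residue number (modified residues such as
#' phosphoserines, stored as HETATM, are included).
#'
#' @param pdbPath PDB file path.
#' @param chain1,resno1 first residue (chain id, author residue number).
#' @param chain2,resno2 second residue.
#' @return minimum distance in Angstrom.
#' @export
minResidueDistance <- function(pdbPath, chain1, resno1, chain2, resno2) {
  pdb <- bio3d::read.pdb(pdbPath, verbose = FALSE)
  at <- pdb$atom
  elem <- ifelse(is.na(at$elesy) | at$elesy == "",
                 substr(gsub("[0-9 ]", "", at$elety), 1, 1), at$elesy)
  at <- at[!toupper(elem) %in% c("H", "D"), , drop = FALSE]
  a <- at[at$chain == chain1 & at$resno == resno1, c("x", "y", "z")]
  b <- at[at$chain == chain2 & at$resno == resno2, c("x", "y", "z")]
  if (!nrow(a) || !nrow(b)) {
    sbStop("siteburden_usage_error",
           "residue %s/%d or %s/%d not found in %s", chain1, resno1,
           chain2, resno2, pdbPath)
  }
  minPairDist(as.matrix(a), as.matrix(b))
}
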
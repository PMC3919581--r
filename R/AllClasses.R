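# Heavy-atom counts of the 20 standard amino acids (N, CA, C, O + side
# chain), used by the synthetic structure generator.
AA_HEAVY_ATOMS <- c(
  G = 4L, A = 5L, S = 6L, C = 6L, T = 7L, V = 7L, P = 7L, L = 8L, I = 8L,
  N = 8L, D = 8L, M = 8L, Q = 9L, E = 9L, K = 9L, H = 10L, F = 11L,
  R = 11L, Y = 12L, W = 14L
)

LIGAND_CATEGORIES <- c("NUC", "PEP", "SMI")

# Contact radius in Angstrom: a residue heavy atom counts as contacting the
# ligand when its distance to any ligand heavy atom is <= this value.
CONTACT_RADIUS <- 4.0

#' StructureChain: one protein chain of a solved structure
#'
#' Holds the one-letter sequence of a structure chain together with its heavy
#' atoms. Residues are numbered 1..L along the chain (re-indexed, not author
#' numbering), so binding annotations are unambiguous.
#'
#' @slot structureId structure identifier (e.g. PDB-style code).
#' @slot chainId single-character chain identifier.
#' @slot sequence one-letter amino-acid sequence of the chain.
#' @slot atoms data.frame with columns \code{resno} (1-based residue index),
#'   \code{aa} (one-letter code), \code{atom} (atom name), \code{x,y,z}
#'   (coordinates in Angstrom). Heavy atoms only.
#' @export
setClass("StructureChain",
  representation(structureId = "character", chainId = "character",
                 sequence = "character", atoms = "data.frame"))

setValidity("StructureChain", function(object) {
  a <- object@atoms
  need <- c("resno", "aa", "atom", "x", "y", "z")
  if (!all(need %in% names(a))) {
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  }
  L <- nchar(object@sequence)
  if (nrow(a)) {
    if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))) {
      return("non-finite atom coordinates")
    }
    if (any(a$resno < 1L | a$resno > L)) {
      return("atom resno outside 1..sequence length")
    }
    seqv <- strsplit(object@sequence, "")[[1]]
    if (any(seqv[a$resno] != a$aa)) {
      return("atom amino acids inconsistent with chain sequence")
    }
  }
  TRUE
})

#' LigandRecord: one bound ligand instance
#'
#' @slot ligandId ligand identifier (residue name, e.g. "ZN").
#' @slot category one of "NUC" (nucleic acid), "PEP" (peptide), "SMI"
#'   (small molecule or ion).
#' @slot atoms numeric matrix (n x 3) of heavy-atom coordinates in Angstrom.
#' @export
setClass("LigandRecord",
  representation(ligandId = "character", category = "character",
                 atoms = "matrix"))

setValidity("LigandRecord", function(object) {
  if (!object@category %in% LIGAND_CATEGORIES) {
    return(sprintf("category must be one of %s",
                   paste(LIGAND_CATEGORIES, collapse = "/")))
  }
  if (nrow(object@atoms) < 1L || ncol(object@atoms) != 3L) {
    return("atoms must be a non-empty n x 3 matrix")
  }
  if (any(!is.finite(object@atoms))) return("non-finite ligand coordinates")
  TRUE
})

#' BindingRecord: annotated binding residues of one chain/ligand pair
#'
#' @slot structureId,chainId the annotated chain.
#' @slot ligand a \linkS4class{LigandRecord}.
#' @slot bindingResidues integer vector of chain residue indices (1-based,
#'   re-indexed chain numbering).
#' @export
setClass("BindingRecord",
  representation(structureId = "character", chainId = "character",
                 ligand = "LigandRecord", bindingResidues = "integer"))

setValidity("BindingRecord", function(object) {
  if (length(object@bindingResidues) < 1L) return("no binding residues")
  if (any(object@bindingResidues < 1L)) return("binding residue index < 1")
  TRUE
})

#' HomologyHit: one sequence-to-structure-chain match with its alignment
#'
#' Identity and coverage are recomputed from the pairwise alignment on
#' construction, never trusted from the hits file.
#'
#' @slot refseqId reference sequence identifier.
#' @slot structureId,chainId the matched chain.
#' @slot eValue BLAST-style expectation value.
#' @slot pctIdentity fraction of aligned (both non-gap) columns that are
#'   identical, in [0,1].
#' @slot structureCoverage fraction of chain residues in aligned columns.
#' @slot alignment data.frame of alignment columns: \code{refPos},
#'   \code{chainPos} (1-based or NA at a gap), \code{refAA}, \code{chainAA}.
#' @export
setClass("HomologyHit",
  representation(refseqId = "character", structureId = "character",
                 chainId = "character", eValue = "numeric",
                 pctIdentity = "numeric", structureCoverage = "numeric",
                 alignment = "data.frame"))

setValidity("HomologyHit", function(object) {
  al <- object@alignment
  if (!all(c("refPos", "chainPos", "refAA", "chainAA") %in% names(al))) {
    return("alignment must have columns refPos, chainPos, refAA, chainAA")
  }
  for (col in c("refPos", "chainPos")) {
    v <- al[[col]][!is.na(al[[col]])]
    if (is.unsorted(v, strictly = TRUE)) {
      return(sprintf("%s not strictly increasing", col))
    }
  }
  if (object@pctIdentity < 0 || object@pctIdentity > 1) {
    return("pctIdentity outside [0,1]")
  }
  if (object@structureCoverage < 0 || object@structureCoverage > 1) {
    return("structureCoverage outside [0,1]")
  }
  TRUE
})

#' StructuralMatch: a filtered homology hit
#'
#' @slot hit the underlying \linkS4class{HomologyHit}.
#' @slot accepted TRUE iff the hit passes the acceptance filter
#'   (E-value < 1e-6, identity > 0.60, structure coverage > 0.80, all strict).
#' @slot reason "accepted" or the first failed filter.
#' @export
setClass("StructuralMatch",
  representation(hit = "HomologyHit", accepted = "logical",
                 reason = "character"))

#' MappedBindingSite: a merged binding site on a reference sequence
#'
#' @slot refseqId reference sequence (gene) identifier.
#' @slot siteId site identifier, unique within refseq.
#' @slot category ligand category ("NUC"/"PEP"/"SMI").
#' @slot positions integer vector of reference-sequence positions.
#' @slot bindingScores named numeric, per-position binding score b in [0,1]
#'   (mean heavy-atom contact fraction over covering structures).
#' @slot sourceStructures character vector of contributing structure chains.
#' @export
setClass("MappedBindingSite",
  representation(refseqId = "character", siteId = "character",
                 category = "character", positions = "integer",
                 bindingScores = "numeric", sourceStructures = "character"))

setValidity("MappedBindingSite", function(object) {
  if (length(object@positions) < 1L) return("empty binding site")
  if (!object@category %in% LIGAND_CATEGORIES) return("bad category")
  b <- object@bindingScores
  if (!identical(sort(as.integer(names(b))), sort(object@positions))) {
    return("bindingScores names must equal positions")
  }
  if (any(b < 0 | b > 1)) return("binding scores outside [0,1]")
  TRUE
})

#' BindingSiteSet: all mapped binding sites plus structural coverage
#'
#' The container produced by \code{\link{annotateReference}}: the merged,
#' scored binding sites of every reference sequence, together with each
#' sequence's "structural positions" (positions covered by at least one
#' accepted structure match) — the sampling universe of the permutation null
#' and the N of the cohort-level hypergeometric test.
#'
#' @slot sites list of \linkS4class{MappedBindingSite}.
#' @slot structuralPositions named list (by refseq) of integer position
#'   vectors covered by accepted matches.
#' @slot refseqLengths named integer vector of protein lengths.
#' @export
setClass("BindingSiteSet",
  representation(sites = "list", structuralPositions = "list",
                 refseqLengths = "integer"))

setValidity("BindingSiteSet", function(object) {
  for (s in object@sites) {
    if (!is(s, "MappedBindingSite")) return("sites must be MappedBindingSite")
    sp <- object@structuralPositions[[s@refseqId]]
    if (is.null(sp) || !all(s@positions %in% sp)) {
      return(sprintf("site %s/%s has positions outside structural coverage",
                     s@refseqId, s@siteId))
    }
  }
  TRUE
})

setMethod("show", "StructureChain", function(object) {
  cat(sprintf("StructureChain %s_%s: %d residues, %d heavy atoms\n",
              object@structureId, object@chainId, nchar(object@sequence),
              nrow(object@atoms)))
})

setMethod("show", "MappedBindingSite", function(object) {
  cat(sprintf("MappedBindingSite %s/%s [%s]: %d residues, mean b = %.3f\n",
              object@refseqId, object@siteId, object@category,
              length(object@positions), mean(object@bindingScores)))
})

setMethod("show", "BindingSiteSet", function(object) {
  cat(sprintf(
    "BindingSiteSet: %d sites on %d reference sequences (%d with coverage)\n",
    length(object@sites),
    length(unique(vapply(object@sites, slot, "", "refseqId"))),
    length(object@structuralPositions)))
})

#' Accessors for BindingSiteSet
#'
#' @param x a \linkS4class{BindingSiteSet}.
#' @param refseqId optional refseq filter.
#' @return \code{bindingSites} returns the list of sites;
#'   \code{structuralPositions} the named list of covered positions.
#' @export
bindingSites <- function(x, refseqId = NULL) {
  stopifnot(is(x, "BindingSiteSet"))
  if (is.null(refseqId)) return(x@sites)
  Filter(function(s) s@refseqId %in% refseqId, x@sites)
}

#' @rdname bindingSites
#' @export
structuralPositions <- function(x, refseqId = NULL) {
  stopifnot(is(x, "BindingSiteSet"))
  if (is.null(refseqId)) x@structuralPositions
  else x@structuralPositions[[refseqId]]
}
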
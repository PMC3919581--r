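test_that("hit filtering applies the strict triple threshold", {
  # identity/coverage derive from the alignments below
  full <- strrep("A", 10)
  hitGood <- makeHit(full, full, eValue = 1e-7)          # id 1, cov 1
  expect_true(filterHits(list(hitGood))[[1]]@accepted)

  # exactly 60% identity is rejected (strict >)
  ref60 <- paste0(strrep("A", 6), strrep("C", 4))
  chain60 <- paste0(strrep("A", 6), strrep("D", 4))
  hit60 <- makeHit(ref60, chain60, eValue = 1e-7)
  expect_equal(hit60@pctIdentity, 0.6)
  m60 <- filterHits(list(hit60))[[1]]
  expect_false(m60@accepted)
  expect_match(m60@reason, "identity")

  # good identity/coverage but weak E-value
  hitE <- makeHit(full, full, eValue = 1e-5)
  mE <- filterHits(list(hitE))[[1]]
  expect_false(mE@accepted)
  expect_match(mE@reason, "e_value")

  # coverage exactly 80% is rejected: chain has 10 residues, 8 aligned
  refCov <- paste0(strrep("A", 8), "--")
  chainCov <- strrep("A", 10)
  hitCov <- makeHit(refCov, chainCov, eValue = 1e-9)
  expect_equal(hitCov@structureCoverage, 0.8)
  expect_false(filterHits(list(hitCov))[[1]]@accepted)
})

test_that("binding-site transfer enforces the strict 90% identity gate", {
  rec <- function(resids) new("BindingRecord", structureId = "S1",
                              chainId = "A", ligand = makeLigand(c(0, 0, 0)),
                              bindingResidues = as.integer(resids))

  # both binding residues identical -> transferred
  m <- acceptedMatch(strrep("A", 10), strrep("A", 10))
  tr <- transferBindingSite(m, rec(c(2, 5)))
  expect_true(tr$transferred)
  expect_equal(tr$positions, c(2L, 5L))

  # 9 of 10 identical: identity exactly 0.90, not > 0.90 -> rejected
  ref <- paste0(strrep("A", 9), "C", strrep("A", 10))
  chain <- paste0(strrep("A", 9), "D", strrep("A", 10))
  m2 <- acceptedMatch(ref, chain)
  tr2 <- transferBindingSite(m2, rec(1:10))
  expect_equal(tr2$bindingIdentity, 0.9)
  expect_false(tr2$transferred)

  # binding residue aligned to a gap counts as non-identical: 3/4 -> reject
  ref3 <- paste0(strrep("A", 9), "-", strrep("A", 10))
  chain3 <- strrep("A", 20)
  m3 <- acceptedMatch(ref3, chain3)
  tr3 <- transferBindingSite(m3, rec(c(1, 2, 3, 10)))
  expect_equal(tr3$bindingIdentity, 0.75)
  expect_false(tr3$transferred)
  # an unaccepted match cannot transfer
  bad <- filterHits(list(makeHit(strrep("A", 10), strrep("A", 10),
                                 eValue = 1)))[[1]]
  expect_error(transferBindingSite(bad, rec(1)), "accepted")
})

test_that("site merging is the transitive closure within a category", {
  s <- function(pos, cat = "SMI") list(category = cat, positions = pos)
  m1 <- mergeSites(list(s(c(1, 2, 3)), s(c(3, 4))))
  expect_length(m1, 1)
  expect_equal(m1[[1]]$positions, 1:4)

  m2 <- mergeSites(list(s(c(1, 2)), s(c(4, 5))))
  expect_length(m2, 2)

  m3 <- mergeSites(list(s(c(1, 2)), s(c(2, 3)), s(c(3, 4))))
  expect_length(m3, 1)
  expect_equal(m3[[1]]$positions, 1:4)

  # cross-category overlap is preserved as two sites
  m4 <- mergeSites(list(s(c(1, 2)), s(c(2, 3), cat = "NUC")))
  expect_length(m4, 2)

  # property: identical partition to brute-force connected components,
  # idempotent, order-independent
  set.seed(31)
  for (rep in 1:20) {
    sites <- lapply(seq_len(sample(2:7, 1)), function(i) {
      s(sort(sample.int(15, sample(2:4, 1))))
    })
    got <- mergeSites(sites)
    # oracle: grow components until fixed point
    comps <- lapply(sites, `[[`, "positions")
    repeat {
      changed <- FALSE
      for (a in seq_along(comps)) {
        for (b in seq_along(comps)) {
          if (a < b && length(intersect(comps[[a]], comps[[b]]))) {
            comps[[a]] <- sort(union(comps[[a]], comps[[b]]))
            comps[[b]] <- integer(0)
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    comps <- Filter(length, comps)
    expect_setequal(lapply(got, `[[`, "positions"), comps)
    # order independence
    perm <- sample(seq_along(sites))
    gotPerm <- mergeSites(sites[perm])
    expect_setequal(lapply(gotPerm, `[[`, "positions"), comps)
    # idempotence
    again <- mergeSites(lapply(got, function(x) {
      list(category = x$category, positions = x$positions)
    }))
    expect_setequal(lapply(again, `[[`, "positions"), comps)
  }
})

test_that("contact counting uses an inclusive 4.0 A radius", {
  chain <- new("StructureChain", structureId = "S1", chainId = "A",
               sequence = "G",
               atoms = data.frame(resno = 1L, aa = "G",
                                  atom = c("N", "CA", "C", "O"),
                                  x = 0, y = 0, z = c(0, 0, 0, 0)))
  onEdge <- contactProfile(chain, makeLigand(c(0, 0, 4.0)), 1L)
  expect_equal(onEdge$nContact, 4L)
  beyond <- contactProfile(chain, makeLigand(c(0, 0, 4.001)), 1L)
  expect_equal(beyond$nContact, 0L)

  chain3 <- new("StructureChain", structureId = "S1", chainId = "A",
                sequence = "G",
                atoms = data.frame(resno = 1L, aa = "G",
                                   atom = c("N", "CA", "C"),
                                   x = c(3, 5, 3.9), y = 0, z = 0))
  prof <- contactProfile(chain3, makeLigand(c(0, 0, 0)), 1L)
  expect_equal(prof$nAtoms, 3L)
  expect_equal(prof$nContact, 2L)
  expect_equal(prof$fraction, 2 / 3)

  # residue without coordinates is skipped with a warning
  expect_warning(p2 <- contactProfile(chain3, makeLigand(c(0, 0, 0)),
                                      c(1L, 2L)), "no coordinates")
  expect_equal(nrow(p2), 1L)
})

test_that("binding scores average per-structure contact fractions", {
  expect_equal(bindingScore(0.5), 0.5)
  expect_equal(bindingScore(c(0.5, 1.0)), 0.75)
  expect_equal(bindingScore(0), 0)  # annotated residue with no contact
  expect_error(bindingScore(numeric(0)), "empty")
  # mean fixed-point: adding a structure at the current mean changes nothing
  expect_equal(bindingScore(c(0.25, 0.75, 0.5)), bindingScore(c(0.25, 0.75)))
})

test_that("annotateReference transfers, merges and scores end to end", {
  # refseq of 12 residues; chain covers positions 3..12 exactly
  refseq <- c(G1 = "MAGGGGGGGGGG")
  chainSeq <- substr(refseq, 3, 12)
  chain <- makeLineChain(chainSeq)
  hit <- makeHit(refseq, paste0("--", chainSeq))
  matches <- filterHits(list(hit))
  # residue j sits at x = 10*(j-1) with G atoms at z = 0..3; each ligand
  # atom is exactly 4.0 A above the top atom of chain residue 8 resp. 9
  # (refseq positions 10 and 11)
  lig <- new("LigandRecord", ligandId = "ZN", category = "SMI",
             atoms = rbind(c(70, 0, 7), c(80, 0, 7)))
  rec <- new("BindingRecord", structureId = "S1", chainId = "A",
             ligand = lig, bindingResidues = c(8L, 9L))
  siteSet <- annotateReference(refseq, matches, list(rec),
                               list(S1_A = chain))
  sites <- bindingSites(siteSet)
  expect_length(sites, 1)
  expect_equal(sites[[1]]@category, "SMI")
  expect_equal(sites[[1]]@positions, c(10L, 11L))
  # one atom of four within 4.0 A -> b = 0.25 at both positions
  expect_equal(unname(sites[[1]]@bindingScores), c(0.25, 0.25))
  # structural positions = chain coverage
  expect_equal(structuralPositions(siteSet, "G1"), 3:12)

  # a rejected hit yields no sites and no structural positions
  weak <- makeHit(refseq, paste0("--", chainSeq), eValue = 1)
  empty <- annotateReference(refseq, filterHits(list(weak)), list(rec),
                             list(S1_A = chain))
  expect_length(bindingSites(empty), 0)
  expect_null(structuralPositions(empty, "G1"))
})

test_that("scores average across structures sharing a position", {
  refseq <- c(G1 = "MAGGGGGGGGGG")
  chainSeq <- substr(refseq, 3, 12)
  mkFix <- function(sid, zLig) {
    chain <- makeLineChain(chainSeq, structureId = sid)
    hit <- makeHit(refseq, paste0("--", chainSeq), structureId = sid)
    lig <- new("LigandRecord", ligandId = "ZN", category = "SMI",
               atoms = matrix(c(70, 0, zLig), nrow = 1))
    rec <- new("BindingRecord", structureId = sid, chainId = "A",
               ligand = lig, bindingResidues = 8L)
    list(chain = chain, hit = hit, rec = rec)
  }
  a <- mkFix("S1", 7)    # 1 of 4 atoms within 4.0 -> fraction 0.25
  b <- mkFix("S2", 5)    # atoms at z 1,2,3 within 4.0 -> fraction 0.75
  siteSet <- annotateReference(refseq, filterHits(list(a$hit, b$hit)),
                               list(a$rec, b$rec),
                               list(S1_A = a$chain, S2_A = b$chain))
  sites <- bindingSites(siteSet)
  expect_length(sites, 1)
  expect_equal(unname(sites[[1]]@bindingScores), 0.5)  # mean(0.25, 0.75)
})

test_that("minimum residue distance is measured on heavy atoms", {
  tmp <- withr::local_tempdir()
  recs <- rbind(
    data.frame(type = "ATOM", atom = c("N", "CA"), resid = "ARG",
               chain = "B", resno = 370, x = c(0, 1), y = 0, z = 0,
               elem = "N"),
    data.frame(type = "ATOM", atom = "H", resid = "ARG", chain = "B",
               resno = 370, x = 0, y = 0, z = 2.0, elem = "H"),
    data.frame(type = "HETATM", atom = c("P", "O1P"), resid = "SEP",
               chain = "C", resno = 33, x = c(0, 0), y = 0,
               z = c(2.4, 5.0), elem = "P"))
  siteburden:::writePdbFile(file.path(tmp, "toy.pdb"), recs)
  d <- minResidueDistance(file.path(tmp, "toy.pdb"), "B", 370, "C", 33)
  # hydrogen at z=2.0 ignored; nearest heavy pair is 2.4 A apart
  expect_equal(d, 2.4, tolerance = 1e-6)
})
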
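test_that("global counts tally distinct positions and pool refseqs", {
  site <- makeSite("G1", c(1, 2, 3), c(1, 1, 1))
  ss <- makeSiteSet(list(site), list(G1 = 1:10))
  v <- data.frame(gene = "G1", protein_pos = c(2L, 2L, 7L))
  counts <- assembleCounts(ss, v)
  expect_equal(counts, list(N = 10L, K = 3L, n = 2L, k = 1L))

  # no variants
  none <- assembleCounts(ss, v[0, ])
  expect_equal(none$n, 0L)
  expect_equal(none$k, 0L)

  # additivity across refseqs: (10,3,2,1) + (5,2,1,1) = (15,5,3,2)
  ss2 <- makeSiteSet(list(site, makeSite("G2", c(1, 2), c(1, 1))),
                     list(G1 = 1:10, G2 = 1:5))
  v2 <- rbind(v, data.frame(gene = "G2", protein_pos = 1L))
  expect_equal(assembleCounts(ss2, v2), list(N = 15L, K = 5L, n = 3L,
                                             k = 2L))

  # category restriction: K and k restricted, N and n global
  ss3 <- makeSiteSet(list(site, makeSite("G1", c(7, 8), c(1, 1),
                                         category = "PEP",
                                         siteId = "PEP_1")),
                     list(G1 = 1:10))
  cPep <- assembleCounts(ss3, v, category = "PEP")
  expect_equal(cPep, list(N = 10L, K = 2L, n = 2L, k = 1L))
})

test_that("hypergeometric tails equal brute-force subset enumeration", {
  # oracle: enumerate all C(N, n) draws of n positions from N, of which K
  # are binding, and count draws by overlap size
  oracleTail <- function(N, K, n, k, tail) {
    draws <- utils::combn(N, n)
    overlap <- apply(draws, 2, function(d) sum(d <= K))
    if (tail == "upper") mean(overlap >= k) else mean(overlap <= k)
  }
  expect_equal(hypergeomTail(list(N = 10L, K = 3L, n = 4L, k = 2L),
                             "upper"), 1 / 3)
  expect_equal(oracleTail(10, 3, 4, 2, "upper"), 1 / 3)
  expect_equal(hypergeomTail(list(N = 10L, K = 3L, n = 4L, k = 0L),
                             "lower"), 1 / 6)
  expect_equal(oracleTail(10, 3, 4, 0, "lower"), 1 / 6)

  set.seed(17)
  for (rep in 1:15) {
    N <- sample(4:11, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    kmax <- min(K, n)
    k <- sample.int(kmax + 1L, 1) - 1L
    counts <- list(N = N, K = K, n = n, k = k)
    for (tail in c("upper", "lower")) {
      expect_equal(hypergeomTail(counts, tail),
                   oracleTail(N, K, n, k, tail), tolerance = 1e-12)
    }
    # complement identity: P(X >= k) + P(X <= k-1) = 1
    if (k >= 1) {
      expect_equal(hypergeomTail(counts, "upper") +
                     hypergeomTail(list(N = N, K = K, n = n, k = k - 1L),
                                   "lower"), 1, tolerance = 1e-12)
    }
  }

  # upper tail monotone non-increasing in k
  ps <- vapply(0:3, function(k) {
    hypergeomTail(list(N = 10L, K = 3L, n = 4L, k = k), "upper")
  }, 1)
  expect_true(all(diff(ps) <= 0))

  # K = 0 forces k = 0 and upper p = 1
  expect_equal(hypergeomTail(list(N = 10L, K = 0L, n = 4L, k = 0L),
                             "upper"), 1)
  # invariant violations error
  expect_error(hypergeomTail(list(N = 10L, K = 3L, n = 4L, k = 4L)),
               class = "siteburden_usage_error")
})

test_that("the binomial frequency test gives exact upper tails", {
  expect_equal(binomialFrequencyTest(4, 4, 0.5), 1 / 16)
  expect_equal(binomialFrequencyTest(0, 12, 0.3), 1)
  oracle <- sum(vapply(5:10, function(i) {
    choose(10, i) * 0.2^i * 0.8^(10 - i)
  }, 1))
  expect_equal(binomialFrequencyTest(5, 10, 0.2), oracle,
               tolerance = 1e-12)
})

test_that("CCG enrichment reproduces direct ratio arithmetic", {
  expect_equal(enrichmentRatio(2, 4, 10, 100), 5.0)
  expect_equal(enrichmentRatio(5, 10, 5, 10), 1.0)
  expect_true(is.na(enrichmentRatio(0, 0, 10, 100)))

  # curve on a constructed cohort: 39 of 1379 mutated sites pass the
  # threshold, 10 of them on curated cancer genes, 104 CCG sites in all
  genes <- sprintf("G%04d", 1:1379)
  ccg <- genes[c(1:10, 40:133)]   # 10 among the selected, 104 total
  res <- data.frame(gene = genes, site_id = "SMI_1", category = "SMI",
                    n_binding_residues = 4L,
                    mutated_binding_positions = 1L, m = 5L, s_b = 1,
                    p_empirical = c(rep(0.001, 39), rep(0.5, 1340)),
                    fdr = NA_real_, cohort = "ALL",
                    stringsAsFactors = FALSE)
  curve <- ccgEnrichmentCurve(res, ccg, thresholds = 0.01)
  expect_equal(curve$selected, 39L)
  expect_equal(curve$ccg_in_selected, 10L)
  expect_equal(curve$background_total, 1379L)
  expect_equal(curve$ccg_in_background, 104L)
  expect_equal(curve$enrichment_ratio, (10 / 39) / (104 / 1379))
  expect_equal(curve$enrichment_ratio, 3.40, tolerance = 1e-3)

  # all genes CCG -> ratio 1 at any threshold
  flat <- ccgEnrichmentCurve(res, genes, thresholds = c(0.01, 0.6))
  expect_equal(flat$enrichment_ratio, c(1, 1))

  # zero selected -> ratio absent
  noneSel <- ccgEnrichmentCurve(res, ccg, thresholds = 1e-6)
  expect_true(is.na(noneSel$enrichment_ratio))

  # gene-level counting collapses multiple sites of one gene
  res2 <- rbind(res, transform(res[1, ], site_id = "SMI_2"))
  curveG <- ccgEnrichmentCurve(res2, ccg, thresholds = 0.01,
                               unit = "gene")
  expect_equal(curveG$selected, 39L)
  expect_equal(curveG$background_total, 1379L)
})

test_that("opposite planting directions give opposite significant tails", {
  # missense on binding sites, SNP-like variants off them
  sites <- list(makeSite("G1", 1:4, rep(1, 4)),
                makeSite("G2", 1:4, rep(1, 4), siteId = "SMI_1"))
  ss <- makeSiteSet(sites, list(G1 = 1:30, G2 = 1:30))
  mis <- data.frame(gene = rep(c("G1", "G2"), each = 4),
                    protein_pos = rep(1:4, 2))
  snp <- data.frame(gene = rep(c("G1", "G2"), each = 15),
                    protein_pos = rep(10:24, 2))
  pMis <- hypergeomTail(assembleCounts(ss, mis), "upper")
  pSnp <- hypergeomTail(assembleCounts(ss, snp), "lower")
  expect_lt(pMis, 0.01)
  expect_lt(pSnp, 0.01)
})
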
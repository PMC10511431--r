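test_that("enrichment score matches hand enumeration", {
  # exponent 0, single-gene set at rank 1 of N = 10: maximal deviation 1
  sc <- setNames(10:1, paste0("g", 1:10))
  expect_equal(enrichmentScore(sc, "g1", exponent = 0)$es, 1)
  # single-gene set at the last rank: most negative just before the hit
  esLast <- enrichmentScore(sc, "g10", exponent = 0)$es
  expect_equal(esLast, bruteES(sc, "g10", exponent = 0))
  expect_equal(esLast, -1)  # nine misses of 1/9 each
  # 5-gene list, scores (5,4,3,2,1), set = ranks 1,2, exponent 1:
  # hits add 5/9 then 4/9; running max is 1 at position 2
  sc5 <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  r <- enrichmentScore(sc5, c("g1", "g2"))
  expect_equal(r$es, 1)
  expect_equal(r$running, c(5 / 9, 1, 2 / 3, 1 / 3, 0), tolerance = 1e-12)

  expect_error(enrichmentScore(sc5, "zz"), "disjoint")
  expect_error(enrichmentScore(sc5, names(sc5)), "degenerate")
})

test_that("ES agrees with brute-force running sums on small random lists", {
  set.seed(5)
  for (i in 1:50) {
    N <- sample(6:10, 1)
    sc <- sort(rnorm(N), decreasing = TRUE)
    names(sc) <- paste0("g", 1:N)
    m <- sample(1:(N - 1), 1)
    set <- sample(names(sc), m)
    for (expo in c(0, 1)) {
      expect_equal(enrichmentScore(sc, set, expo)$es,
                   bruteES(sc, set, expo), tolerance = 1e-12)
    }
  }
})

test_that("ES agrees with the fgsea reference statistic", {
  skip_if_not_installed("fgsea")
  set.seed(6)
  sc <- sort(rnorm(500), decreasing = TRUE)
  names(sc) <- paste0("g", 1:500)
  for (i in 1:10) {
    set <- sample(names(sc), sample(10:50, 1))
    ours <- enrichmentScore(sc, set)$es
    ref <- fgsea::calcGseaStat(sc, selectedStats = which(names(sc) %in% set),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("reversing the ranked list negates the unweighted ES", {
  set.seed(12)
  sc <- sort(rnorm(40), decreasing = TRUE)
  names(sc) <- paste0("g", 1:40)
  set <- sample(names(sc), 8)
  fwd <- enrichmentScore(sc, set, exponent = 0)$es
  revd <- setNames(sort(-sc, decreasing = TRUE), rev(names(sc)))
  bwd <- enrichmentScore(revd, set, exponent = 0)$es
  expect_equal(bwd, -fwd, tolerance = 1e-12)
})

test_that("permutation normalisation is reproducible and sign-consistent", {
  set.seed(3)
  sc <- sort(rnorm(300), decreasing = TRUE)
  names(sc) <- paste0("g", 1:300)
  gc <- GeneSetCollection(list(TOP = names(sc)[1:20],
                               BOT = names(sc)[281:300],
                               DUP_OF_TOP = names(sc)[1:20],
                               RAND = sample(names(sc), 20)))
  r1 <- normalizedEnrichment(sc, gc, nPerm = 200, seed = 11)
  r2 <- normalizedEnrichment(sc, gc, nPerm = 200, seed = 11)
  expect_identical(r1, r2)
  # duplicate set under another name: identical ES and (same seed) NES
  expect_equal(r1$ES[r1$geneset == "DUP_OF_TOP"],
               r1$ES[r1$geneset == "TOP"])
  expect_equal(r1$NES[r1$geneset == "DUP_OF_TOP"],
               r1$NES[r1$geneset == "TOP"])
  # sign(NES) = sign(ES); q in [0,1]
  ok <- !is.na(r1$NES) & r1$ES != 0
  expect_true(all(sign(r1$NES[ok]) == sign(r1$ES[ok])))
  expect_true(all(r1$q >= 0 & r1$q <= 1, na.rm = TRUE))
  expect_gt(r1$NES[r1$geneset == "TOP"], 0)
  expect_lt(r1$NES[r1$geneset == "BOT"], 0)
})

test_that("pan-cancer significance keeps sets passing in any context", {
  res <- data.frame(
    geneset = c("A", "A", "B", "B"),
    NES = c(2.4, 0.2, 2.4, 2.4),
    q = c(0.0005, 0.9, 0.002, 0.002),
    context = c("X", "Y", "X", "Y"))
  out <- significantGenesets(res)
  expect_setequal(unique(out$geneset), "A")   # B never passes q < 0.001
  expect_equal(nrow(out), 2L)                 # both contexts retained for A
  expect_equal(out$passes, c(TRUE, FALSE))
  # below-threshold NES never reported
  res2 <- res; res2$NES <- c(2.2, 2.2, 2.2, 2.2); res2$q <- 1e-5
  expect_equal(nrow(significantGenesets(res2)), 0L)
})

test_that("collection assembly preserves provenance and rejects collisions", {
  a <- GeneSetCollection(list(H1 = c("x", "y")), provenance = "hallmark")
  b <- GeneSetCollection(list(P1 = c("z", "w"), P2 = c("q", "r")),
                         provenance = "panther")
  m <- assembleCollection(a, b)
  expect_equal(length(m), 3L)
  expect_equal(unname(setProvenance(m)[["P2"]]), "panther")
  expect_error(assembleCollection(a, a), "collision")
  # merged collection round-trips through GMT
  f <- tempfile(fileext = ".gmt")
  writeGmt(m, f)
  expect_equal(geneSets(readGmt(f)), geneSets(m))
})
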
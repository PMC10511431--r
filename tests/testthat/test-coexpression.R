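test_that("gene filter applies strict mean/SD thresholds per cancer type", {
  expr <- rbind(
    CONST = rep(1.0, 8),             # SD 0: dropped
    GOOD = c(0.9, 0.3, 0.8, 0.4, 0.1, 0.1, 0.1, 0.1),  # passes in group A
    LOWM = c(0.1, 0.2, 0.1, 0.2, 0.1, 0.2, 0.1, 0.2))  # mean too low
  colnames(expr) <- paste0("s", 1:8)
  groups <- setNames(rep(c("A", "B"), each = 4), colnames(expr))
  kept <- filterGenes(expr, groups)
  expect_equal(kept, "GOOD")
  # boundary is strict: mean 0.6, SD 0.25 in one type only is kept
  m <- mean(c(0.9, 0.3, 0.8, 0.4)); s <- sd(c(0.9, 0.3, 0.8, 0.4))
  expect_true(m > 0.5 && s > 0.2)
  # query gene is force-retained with a warning
  expect_warning(k2 <- filterGenes(expr, groups, queryGene = "CONST"),
                 "force-retained")
  expect_true("CONST" %in% k2)
  expect_error(filterGenes(expr, rep(NA_character_, 8)), "empty")
})

test_that("Spearman rho matches a brute-force rank oracle", {
  # fixed hand-rankable pair: d^2 sums to 4, so rho = 1 - 24/120 = 0.8
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  expect_equal(bruteSpearman(x, y), 0.8)
  expr <- rbind(Q = x, G = y)
  colnames(expr) <- paste0("s", 1:5)
  pr <- spearmanProfile(expr, "Q", context = "toy")
  expect_equal(pr$rho[pr$gene == "G"], 0.8)

  # randomized vectors, including ties
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    a <- sample(1:8, n, replace = TRUE)  # ties exercised via mid-ranks
    b <- rnorm(n)
    e <- rbind(Q = a, G = b)
    colnames(e) <- paste0("s", 1:n)
    pr <- spearmanProfile(e, "Q")
    expect_equal(pr$rho, bruteSpearman(b, a), tolerance = 1e-12)
  }
})

test_that("profile q-values follow the textbook BH step-up", {
  # the printed example: p = (.01,.02,.03,.04) over 4 genes -> all q = .04
  expect_equal(bruteBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  spec <- tinySpec(nSamples = 40, nGenes = 60, seed = 9)
  sim <- generateCohort(spec)
  ids <- sim$annotations$sample_id[sim$annotations$cancer_type == "TT01"]
  pr <- spearmanProfile(sim$expr, "QGENE", ids)
  inFam <- !is.na(pr$p)
  expect_equal(pr$q[inFam], bruteBH(pr$p[inFam]), tolerance = 1e-12)
  # rejection at q <= alpha equals the step-up rule
  alpha <- 0.05
  p <- sort(pr$p[inFam]); n <- length(p)
  kmax <- suppressWarnings(max(which(p <= alpha * seq_len(n) / n)))
  stepUpReject <- if (is.finite(kmax)) p <= p[kmax] else rep(FALSE, n)
  expect_equal(sort(pr$p[inFam][pr$q[inFam] <= alpha]),
               p[stepUpReject])
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(4)
  expr <- rbind(Q = rnorm(30), G1 = rnorm(30), G2 = rnorm(30))
  colnames(expr) <- paste0("s", 1:30)
  base <- spearmanProfile(expr, "Q")
  warped <- expr
  warped["G1", ] <- exp(3 * warped["G1", ])        # monotone on a gene
  warped["Q", ] <- log10(1 + exp(warped["Q", ]))   # monotone on the query
  tr <- spearmanProfile(warped, "Q")
  expect_equal(tr$rho, base$rho, tolerance = 1e-12)
})

test_that("the query gene is excluded and degenerate genes leave the BH family", {
  expr <- rbind(Q = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
                COPY = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
                FLAT = rep(2, 12))
  colnames(expr) <- paste0("s", 1:12)
  pr <- spearmanProfile(expr, "Q")
  expect_false("Q" %in% pr$gene)
  expect_equal(pr$rho[pr$gene == "COPY"], 1)
  expect_true(is.na(pr$rho[pr$gene == "FLAT"]))
  expect_true(is.na(pr$q[pr$gene == "FLAT"]))
  expect_error(spearmanProfile(expr, "NOPE"), "absent")
})

test_that("pairwise-complete handling ignores masked cells", {
  set.seed(8)
  expr <- rbind(Q = rnorm(40), G = rnorm(40))
  colnames(expr) <- paste0("s", 1:40)
  expr["G", c(3, 17, 25)] <- NA
  pr <- spearmanProfile(expr, "Q")
  ok <- !is.na(expr["G", ])
  expect_equal(pr$n_pairs, sum(ok))
  expect_equal(pr$rho, bruteSpearman(expr["G", ok], expr["Q", ok]),
               tolerance = 1e-12)
  # fewer than 3 complete pairs: rho stays missing
  expr2 <- expr
  expr2["G", 3:40] <- NA
  pr2 <- spearmanProfile(expr2, "Q")
  expect_true(is.na(pr2$rho))
})

test_that("screen lists, unions and idempotence behave", {
  prof <- data.frame(gene = c("a", "b", "c", "d"),
                     rho = c(0.7, -0.65, 0.2, NA),
                     p = c(0.001, 0.001, 0.5, NA),
                     q = c(0.004, 0.004, 0.5, NA), n_pairs = 50)
  sg <- significantGenes(prof)
  expect_equal(sg$positive, "a")
  expect_equal(sg$negative, "b")
  low <- prof; low$rho <- c(0.5, -0.5, 0.1, 0.2)
  expect_equal(significantGenes(low)$counts[["total"]], 0)

  p1 <- data.frame(gene = letters[1:6], rho = c(0.9, 0.8, 0.7, 0, 0, 0),
                   p = 0.01, q = 0.01, n_pairs = 50)
  p2 <- data.frame(gene = letters[1:6], rho = c(0, 0, 0, -0.7, -0.8, -0.9),
                   p = 0.01, q = 0.01, n_pairs = 50)
  p3 <- data.frame(gene = letters[1:6], rho = c(0, 0, 0, -0.7, 0.1, 0.1),
                   p = 0.01, q = 0.01, n_pairs = 50)
  u <- unionCorrelatedGenes(list(X = p1, Y = p2))
  expect_equal(u$genes, letters[1:6])       # disjoint 3 + 3
  u2 <- unionCorrelatedGenes(list(X = p2, Y = p2))
  expect_equal(u2$genes, letters[4:6])      # idempotent
  u3 <- unionCorrelatedGenes(list(X = p2, Y = p3))
  expect_equal(u3$genes, letters[4:6])
  expect_equal(dim(u$rhoMatrix), c(6L, 2L))
  expect_equal(u$rhoMatrix["a", "X"], 0.9)
})

test_that("counts-vs-level correlation behaves on degenerate and monotone input", {
  counts <- data.frame(cancer_type = paste0("T", 1:10),
                       total = 1:10, positive = 1:10, negative = rep(2, 10))
  lvl <- setNames(seq(0.1, 1, 0.1), counts$cancer_type)
  out <- countsVsLevel(counts, lvl)
  expect_equal(out[["total"]], 1)       # strictly monotone
  expect_true(is.na(out[["negative"]])) # zero variance reported missing
  expect_error(countsVsLevel(counts[1:2, ], lvl), "at least 3")
})
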
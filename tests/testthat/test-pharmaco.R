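toyPanel <- function() {
  # 3 cancer types with 1, 2 and 5 tumor lines plus decoys
  meta <- data.frame(
    cell_line = c("a1", "b1", "b2", "c1", "c2", "c3", "c4", "c5",
                  "e1", "f1"),
    cancer_type = c("A", "B", "B", "C", "C", "C", "C", "C", "E", "F"),
    lineage = c(rep("Tumor", 8), "Engineered", "Fibroblast"),
    stringsAsFactors = FALSE)
  expr <- matrix(seq(0.1, 1, length.out = 10), 1, 10,
                 dimnames = list("Q", meta$cell_line))
  CellLinePanel(expr, meta)
}

test_that("panel filtering removes decoys and singleton cancer types", {
  suppressMessages(fp <- filterPanel(toyPanel()))
  meta <- lineMeta(fp)
  expect_setequal(unique(meta$cancer_type), c("B", "C"))
  expect_false(any(meta$lineage %in% c("Engineered", "Fibroblast")))
  expect_equal(attr(fp, "n_lines_removed"), 2L)

  allFib <- CellLinePanel(
    matrix(1:2, 1, 2, dimnames = list("Q", c("x", "y"))),
    data.frame(cell_line = c("x", "y"), cancer_type = "A",
               lineage = "Fibroblast"))
  expect_error(suppressMessages(filterPanel(allFib)), "no cell lines")
})

test_that("drug screen eligibility gates match the written rule exactly", {
  mkPanel <- function(aucByLine) {
    n <- length(aucByLine)
    meta <- data.frame(cell_line = paste0("L", seq_len(n)),
                       cancer_type = "A", lineage = "Tumor")
    expr <- matrix(rnorm(n), 1, n, dimnames = list("Q", meta$cell_line))
    auc <- data.frame(cell_line = meta$cell_line, compound = "drug",
                      auc = aucByLine)
    CellLinePanel(expr, meta, auc)
  }
  # 9 tested lines: ineligible regardless of spread
  out9 <- drugScreen(mkPanel(c(0.1, 0.2, 0.3, 0.9, 0.9, 0.9, 0.5, 0.5,
                               0.5)), "Q")
  expect_false(out9$eligible)
  expect_true(is.na(out9$rho))
  # 12 lines all resistant: no sensitive lines
  out12 <- drugScreen(mkPanel(rep(0.9, 12)), "Q")
  expect_false(out12$eligible)
  # boundary: exactly 10 lines, 2 sensitive, 2 resistant
  okAuc <- c(0.7, 0.7, 0.85, 0.85, rep(0.8, 6))
  outOk <- drugScreen(mkPanel(okAuc), "Q")
  expect_true(outOk$eligible)
  expect_false(is.na(outOk$rho))
  expect_error(drugScreen(mkPanel(okAuc), "NOPE"), "absent")
})

test_that("screen matches a brute-force reimplementation on a toy table", {
  set.seed(51)
  meta <- data.frame(cell_line = paste0("L", 1:36),
                     cancer_type = rep(c("A", "B", "C"), each = 12),
                     lineage = "Tumor", stringsAsFactors = FALSE)
  expr <- matrix(rnorm(36), 1, 36, dimnames = list("Q", meta$cell_line))
  rows <- expand.grid(cell_line = meta$cell_line,
                      compound = paste0("d", 1:4),
                      stringsAsFactors = FALSE)
  rows$auc <- round(runif(nrow(rows)), 2)
  rows$auc[sample(nrow(rows), 40)] <- NA  # untested pairs
  panel <- CellLinePanel(expr, meta, rows)
  out <- drugScreen(panel, "Q")
  expect_equal(nrow(out), 12L)
  for (i in seq_len(nrow(out))) {
    sub <- rows[rows$compound == out$compound[i] &
                  meta$cancer_type[match(rows$cell_line,
                                         meta$cell_line)] ==
                  out$cancer_type[i] & !is.na(rows$auc), ]
    expect_equal(out$n_lines[i], nrow(sub))
    expect_equal(out$n_sensitive[i], sum(sub$auc < 0.8))
    expect_equal(out$n_resistant[i], sum(sub$auc > 0.8))
    elig <- nrow(sub) >= 10 && sum(sub$auc < 0.8) >= 2 &&
      sum(sub$auc > 0.8) >= 2
    expect_equal(out$eligible[i], elig)
    if (elig)
      expect_equal(out$rho[i],
                   cor(expr["Q", sub$cell_line], sub$auc,
                       method = "spearman"), tolerance = 1e-12)
  }
})

test_that("rho sign flips under the response orientation AUC -> 1 - AUC", {
  set.seed(52)
  meta <- data.frame(cell_line = paste0("L", 1:20), cancer_type = "A",
                     lineage = "Tumor")
  expr <- matrix(rnorm(20), 1, 20, dimnames = list("Q", meta$cell_line))
  auc <- data.frame(cell_line = meta$cell_line, compound = "d",
                    auc = runif(20, 0.5, 0.95))
  p1 <- CellLinePanel(expr, meta, auc)
  auc2 <- auc; auc2$auc <- 1 - auc2$auc
  p2 <- CellLinePanel(expr, meta, auc2)
  r1 <- drugScreen(p1, "Q")
  r2 <- drugScreen(p2, "Q", aucSensCut = 0.2)  # mirrored cutoff
  expect_equal(r2$rho, -r1$rho, tolerance = 1e-12)
})

test_that("eligibility is monotone in added tested lines", {
  base <- c(0.7, 0.7, 0.85, 0.85, rep(0.8, 6))
  for (extra in c(0.1, 0.5, 0.8, 0.95)) {
    meta <- data.frame(cell_line = paste0("L", 1:11), cancer_type = "A",
                       lineage = "Tumor")
    expr <- matrix(rnorm(11), 1, 11, dimnames = list("Q", meta$cell_line))
    auc <- data.frame(cell_line = meta$cell_line, compound = "d",
                      auc = c(base, extra))
    expect_true(drugScreen(CellLinePanel(expr, meta, auc), "Q")$eligible)
  }
})

test_that("reportable compounds respect the minimum-type boundary", {
  tab <- expand.grid(compound = c("x", "y"),
                     cancer_type = paste0("T", 1:11),
                     stringsAsFactors = FALSE)
  tab$source <- "s"; tab$n_lines <- 12; tab$n_sensitive <- 3
  tab$n_resistant <- 3
  tab$eligible <- TRUE
  tab$eligible[tab$compound == "y" & tab$cancer_type == "T11"] <- FALSE
  tab$rho <- 0.4
  tab$rho[!tab$eligible] <- NA
  out <- reportableCompounds(tab, minTypes = 11)
  expect_equal(out$compounds, "x")   # y is eligible in only 10 types
  expect_equal(dim(out$rhoMatrix), c(1L, 11L))
  out10 <- reportableCompounds(tab, minTypes = 10)
  expect_setequal(out10$compounds, c("x", "y"))
})

test_that("mRNA-protein correlation sums channels and validates overlap", {
  meta <- data.frame(cell_line = paste0("L", 1:6), cancer_type = "A",
                     lineage = "Tumor")
  expr <- matrix(1:6, 1, 6, dimnames = list("Q", meta$cell_line))
  prot <- rbind(Q_iso1 = (1:6) / 3, Q_iso2 = (1:6) / 3,
                Q_iso3 = (1:6) / 3)
  colnames(prot) <- meta$cell_line
  panel <- CellLinePanel(expr, meta, protein = prot)
  mp <- mrnaProteinCorrelation(panel, "Q")
  expect_equal(mp$cor, 1)            # protein is an exact copy of mRNA
  expect_equal(mp$n, 6L)
  expect_error(mrnaProteinCorrelation(panel, "Q", proteinIds = "nope"),
               "not found")
  noProt <- CellLinePanel(expr, meta)
  expect_error(mrnaProteinCorrelation(noProt, "Q"), "no protein")
})
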
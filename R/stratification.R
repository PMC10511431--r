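#' Compare query-gene expression between TP53 groups per cancer type
#'
#' Two-sided Student's t-test (pooled variance) between mutation groups,
#' run separately in every cancer type and for every group pair. Groups with
#' fewer than 2 samples are skipped with a notice.
#'
#' @param exprVec Named numeric vector of query-gene expression (names =
#'   sample ids).
#' @param ann Annotation data.frame with `sample_id`, `cancer_type` and the
#'   grouping column.
#' @param grouping `"status"` (WT vs MUT) or `"class"` (WT vs TruncatingHomDel
#'   vs InframeMissense, all pairs).
#' @return data.frame with one row per (cancer type, group pair): group
#'   means/SDs/sizes, pooled-variance `t` and two-sided `p`.
#' @export
compareExpressionByStatus <- function(exprVec, ann,
                                      grouping = c("status", "class")) {
  grouping <- match.arg(grouping)
  col <- if (grouping == "status") "tp53_status" else "tp53_class"
  stopifnot(all(c("sample_id", "cancer_type", col) %in% names(ann)))
  ann <- ann[ann$sample_id %in% names(exprVec), , drop = FALSE]
  ann <- ann[!is.na(ann[[col]]) & ann[[col]] != "Unknown", , drop = FALSE]
  rows <- list()
  for (ct in unique(ann$cancer_type)) {
    sub <- ann[ann$cancer_type == ct, , drop = FALSE]
    lv <- unique(sub[[col]])
    if (length(lv) < 2L) next
    for (pair in utils::combn(sort(lv), 2L, simplify = FALSE)) {
      x <- exprVec[sub$sample_id[sub[[col]] == pair[1L]]]
      y <- exprVec[sub$sample_id[sub[[col]] == pair[2L]]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2L || length(y) < 2L) {
        message("skipping ", ct, " ", pair[1L], " vs ", pair[2L],
                ": a group has fewer than 2 samples")
        next
      }
      tt <- t.test(x, y, var.equal = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        cancer_type = ct, group1 = pair[1L], group2 = pair[2L],
        n1 = length(x), n2 = length(y),
        mean1 = mean(x), mean2 = mean(y), sd1 = sd(x), sd2 = sd(y),
        t = unname(tt$statistic), p = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cancer types eligible for TP53-stratified analysis
#'
#' Returns the cancer types with more than `minPerGroup` samples in each of
#' the WT and MUT strata (strict `>` by default; set `inclusive = TRUE` for
#' `>=`). Samples with unknown status are ignored.
#'
#' @param ann Annotation data.frame with `cancer_type` and `tp53_status`.
#' @param minPerGroup Per-stratum size gate (default 20).
#' @param inclusive Use `>=` instead of `>`.
#' @return Character vector of eligible cancer-type acronyms.
#' @export
eligibleContexts <- function(ann, minPerGroup = 20, inclusive = FALSE) {
  ok <- !is.na(ann$tp53_status) & ann$tp53_status %in% c("WT", "MUT")
  tab <- table(ann$cancer_type[ok], ann$tp53_status[ok])
  if (!all(c("WT", "MUT") %in% colnames(tab))) return(character())
  cmp <- if (inclusive) `>=` else `>`
  rownames(tab)[cmp(tab[, "WT"], minPerGroup) & cmp(tab[, "MUT"], minPerGroup)]
}

#' Per-gene correlation delta between TP53 strata
#'
#' Computes, gene by gene, `delta = rho_MUT - rho_WT` between two correlation
#' profiles of the same cancer type, and flags genes whose absolute delta
#' exceeds the threshold. Genes present in only one stratum (or with missing
#' rho) are excluded and counted.
#'
#' @param profileWt,profileMut [spearmanProfile()] outputs for the WT and MUT
#'   strata of one cancer type.
#' @param threshold Absolute delta cutoff (default 0.6).
#' @return data.frame with `gene`, `rho_wt`, `rho_mut`, `delta`,
#'   `significant`; attribute `n_excluded`.
#' @export
deltaCorrelation <- function(profileWt, profileMut, threshold = 0.6) {
  m <- merge(profileWt[, c("gene", "rho")], profileMut[, c("gene", "rho")],
             by = "gene", suffixes = c("_wt", "_mut"))
  nTotal <- length(union(profileWt$gene, profileMut$gene))
  ok <- !is.na(m$rho_wt) & !is.na(m$rho_mut)
  excluded <- nTotal - sum(ok)
  m <- m[ok, , drop = FALSE]
  out <- data.frame(gene = m$gene, rho_wt = m$rho_wt, rho_mut = m$rho_mut,
                    delta = m$rho_mut - m$rho_wt, stringsAsFactors = FALSE)
  out$significant <- abs(out$delta) > threshold
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}

#' Per-geneset NES delta between TP53 strata
#'
#' `delta = NES_MUT - NES_WT` for every geneset evaluated in both strata,
#' with two thresholds: `deltaMinAbs` marks significance and `reportMinAbs`
#' marks figure-level reporting. Sets evaluated in only one stratum are
#' excluded and counted.
#'
#' @param gseaWt,gseaMut [normalizedEnrichment()] outputs for the two strata.
#' @param deltaMinAbs Significance cutoff on `|delta|` (default 0.6).
#' @param reportMinAbs Reporting cutoff on `|delta|` (default 2.3).
#' @return data.frame with `geneset`, `nes_wt`, `nes_mut`, `delta`,
#'   `significant`, `reported`; attribute `n_excluded`.
#' @export
deltaNes <- function(gseaWt, gseaMut, deltaMinAbs = 0.6, reportMinAbs = 2.3) {
  m <- merge(gseaWt[, c("geneset", "NES")], gseaMut[, c("geneset", "NES")],
             by = "geneset", suffixes = c("_wt", "_mut"))
  nTotal <- length(union(gseaWt$geneset, gseaMut$geneset))
  ok <- !is.na(m$NES_wt) & !is.na(m$NES_mut)
  excluded <- nTotal - sum(ok)
  m <- m[ok, , drop = FALSE]
  out <- data.frame(geneset = m$geneset, nes_wt = m$NES_wt,
                    nes_mut = m$NES_mut, delta = m$NES_mut - m$NES_wt,
                    stringsAsFactors = FALSE)
  out$significant <- abs(out$delta) > deltaMinAbs
  out$reported <- abs(out$delta) > reportMinAbs
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}

#' Stratified correlation profiles for the eligible cancer types
#'
#' Runs [spearmanProfile()] separately in the WT and MUT strata of every
#' eligible cancer type. Samples with unknown TP53 status are excluded from
#' the stratified profiles (they remain in any ALL-stratum analysis). No
#' output is produced for ineligible contexts.
#'
#' @param expr Gene-by-sample matrix.
#' @param ann Annotation data.frame.
#' @param queryGene Query gene symbol.
#' @param minPerGroup,inclusive Passed to [eligibleContexts()].
#' @return Named list (by cancer type) of lists with `WT` and `MUT` profiles.
#' @export
stratifiedProfiles <- function(expr, ann, queryGene, minPerGroup = 20,
                               inclusive = FALSE) {
  elig <- eligibleContexts(ann, minPerGroup, inclusive)
  out <- list()
  for (ct in elig) {
    res <- list()
    for (st in c("WT", "MUT")) {
      ids <- ann$sample_id[ann$cancer_type == ct &
                             !is.na(ann$tp53_status) &
                             ann$tp53_status == st]
      ids <- intersect(ids, colnames(expr))
      res[[st]] <- spearmanProfile(expr, queryGene, ids,
                                   context = paste0(ct, ":", st))
    }
    out[[ct]] <- res
  }
  out
}
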
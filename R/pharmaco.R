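#' Filter a cell-line panel for the pharmacogenomic screen
#'
#' Removes cell lines flagged as engineered or fibroblast, then removes
#' cancer types left with one or zero lines in the expression data. Counts of
#' removed lines and types are reported via `message()` and stored as
#' attributes.
#'
#' @param panel A [CellLinePanel-class].
#' @return A filtered [CellLinePanel-class] with attributes
#'   `n_lines_removed` and `n_types_removed`.
#' @export
filterPanel <- function(panel) {
  meta <- lineMeta(panel)
  keep <- !meta$lineage %in% c("Engineered", "Fibroblast")
  nLineage <- sum(!keep)
  meta <- meta[keep, , drop = FALSE]
  typeCounts <- table(meta$cancer_type)
  goodTypes <- names(typeCounts)[typeCounts > 1L]
  nTypes <- length(typeCounts) - length(goodTypes)
  meta <- meta[meta$cancer_type %in% goodTypes, , drop = FALSE]
  if (!nrow(meta)) stop("no cell lines remain after filtering")
  message("filterPanel: removed ", nLineage, " engineered/fibroblast lines",
          " and ", nTypes, " singleton cancer types; ", nrow(meta),
          " lines from ", length(goodTypes), " types retained")
  expr <- panelExpr(panel)[, intersect(colnames(panelExpr(panel)),
                                       meta$cell_line), drop = FALSE]
  auc <- drugAuc(panel)
  auc <- auc[auc$cell_line %in% meta$cell_line, , drop = FALSE]
  prot <- proteinAbundance(panel)
  if (!is.null(prot))
    prot <- prot[, intersect(colnames(prot), meta$cell_line), drop = FALSE]
  out <- CellLinePanel(expr, meta, auc, prot)
  attr(out, "n_lines_removed") <- nLineage
  attr(out, "n_types_removed") <- nTypes
  out
}

#' Expression-vs-drug-response correlation screen
#'
#' For every (compound, cancer type) pair, eligibility is evaluated on the
#' lines with an observed AUC: at least `minLines` lines tested, at least
#' `minEachClass` sensitive (AUC < `aucSensCut`) and at least `minEachClass`
#' resistant (AUC > `aucSensCut`). Spearman rho between query-gene expression
#' and AUC is computed only for eligible pairs; positive rho means high
#' expression goes with resistance (higher AUC).
#'
#' @param panel A filtered [CellLinePanel-class] with AUC data.
#' @param queryGene Query gene symbol (must be in the panel expression).
#' @param aucSensCut Sensitivity cutoff on AUC (default 0.8).
#' @param minLines Minimum tested lines (default 10).
#' @param minEachClass Minimum sensitive and resistant lines (default 2).
#' @return data.frame with one row per (compound, cancer type, source):
#'   `n_lines`, `n_sensitive`, `n_resistant`, `eligible`, `rho` (`NA` when
#'   ineligible).
#' @export
drugScreen <- function(panel, queryGene, aucSensCut = 0.8, minLines = 10,
                       minEachClass = 2) {
  expr <- panelExpr(panel)
  if (!queryGene %in% rownames(expr))
    stop("query gene '", queryGene, "' absent from panel expression")
  meta <- lineMeta(panel)
  auc <- drugAuc(panel)
  auc <- auc[!is.na(auc$auc), , drop = FALSE]
  if (!"source" %in% names(auc)) auc$source <- "default"
  qexpr <- setNames(expr[queryGene, ], colnames(expr))
  auc$cancer_type <- meta$cancer_type[match(auc$cell_line, meta$cell_line)]
  keyList <- split(auc, list(auc$compound, auc$cancer_type, auc$source),
                   drop = TRUE)
  rows <- lapply(keyList, function(d) {
    d <- d[d$cell_line %in% names(qexpr), , drop = FALSE]
    nl <- nrow(d)
    ns <- sum(d$auc < aucSensCut)
    nr <- sum(d$auc > aucSensCut)
    eligible <- nl >= minLines && ns >= minEachClass && nr >= minEachClass
    rho <- NA_real_
    if (eligible) {
      x <- qexpr[d$cell_line]
      rho <- suppressWarnings(cor(x, d$auc, method = "spearman"))
    }
    data.frame(compound = d$compound[1L], cancer_type = d$cancer_type[1L],
               source = d$source[1L], n_lines = nl, n_sensitive = ns,
               n_resistant = nr, eligible = eligible, rho = rho,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compounds eligible in enough cancer types, heatmap-ready
#'
#' Keeps the compounds whose (compound, cancer type) screen was eligible in
#' at least `minTypes` cancer types and assembles the compound-by-type rho
#' matrix, with `NA` cells for ineligible pairs.
#'
#' @param screenTable Output of [drugScreen()].
#' @param minTypes Minimum eligible cancer types (default 11).
#' @return List with `compounds` (character vector) and `rhoMatrix`
#'   (compound x cancer type).
#' @export
reportableCompounds <- function(screenTable, minTypes = 11) {
  el <- screenTable[screenTable$eligible, , drop = FALSE]
  byComp <- tapply(el$cancer_type, el$compound,
                   function(x) length(unique(x)))
  compounds <- sort(names(byComp)[byComp >= minTypes])
  types <- sort(unique(screenTable$cancer_type))
  rhoMatrix <- matrix(NA_real_, length(compounds), length(types),
                      dimnames = list(compounds, types))
  for (i in seq_len(nrow(el))) {
    if (el$compound[i] %in% compounds)
      rhoMatrix[el$compound[i], el$cancer_type[i]] <- el$rho[i]
  }
  list(compounds = compounds, rhoMatrix = rhoMatrix)
}

#' Correlation of query mRNA with its summed protein channels
#'
#' Sums the listed protein channels (e.g. isoform rows) per cell line and
#' correlates the summed signal with query-gene expression over complete
#' pairs.
#'
#' @param panel A [CellLinePanel-class] with protein data.
#' @param queryGene Query gene symbol.
#' @param proteinIds Row names of the protein channels to sum (default: all
#'   channels whose name starts with the query gene symbol).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `cor`, `n`, and `data` (per-line mRNA and protein).
#' @export
mrnaProteinCorrelation <- function(panel, queryGene, proteinIds = NULL,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  expr <- panelExpr(panel)
  prot <- proteinAbundance(panel)
  if (is.null(prot)) stop("panel has no protein data")
  if (!queryGene %in% rownames(expr))
    stop("query gene '", queryGene, "' absent from panel expression")
  if (is.null(proteinIds))
    proteinIds <- grep(paste0("^", queryGene), rownames(prot), value = TRUE)
  missing <- setdiff(proteinIds, rownames(prot))
  if (length(missing)) stop("protein channels not found: ",
                            paste(missing, collapse = ", "))
  shared <- intersect(colnames(expr), colnames(prot))
  if (length(shared) < 3L) stop("fewer than 3 lines with both measurements")
  pSum <- colSums(prot[proteinIds, shared, drop = FALSE])
  mrna <- expr[queryGene, shared]
  ok <- !is.na(pSum) & !is.na(mrna)
  if (sum(ok) < 3L) stop("fewer than 3 complete mRNA-protein pairs")
  r <- cor(mrna[ok], pSum[ok], method = method)
  list(cor = r, n = sum(ok),
       data = data.frame(cell_line = shared[ok], mrna = mrna[ok],
                         protein = pSum[ok], stringsAsFactors = FALSE))
}
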
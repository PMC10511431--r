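#' @import methods
#' @importFrom stats cor cor.test t.test p.adjust median sd quantile rnorm
#'   runif rbinom rexp setNames complete.cases kmeans uniroot plogis pt
#'   pchisq hclust cutree as.dist dist
#' @importFrom graphics hist
#' @importFrom utils read.delim write.table head combn
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Collection of named genesets
#'
#' A named list of gene symbol vectors with a provenance label per set.
#' Set names are unique and no set is empty; genes within a set are unique.
#'
#' @slot sets Named list of character vectors of gene symbols.
#' @slot provenance Character vector, one label per set (e.g. the source
#'   collection a set came from).
#'
#' @seealso [readGmt()], [writeGmt()], [assembleCollection()],
#'   [buildKoSignature()]
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", provenance = "character"))

setValidity("GeneSetCollection", function(object) {
  s <- object@sets
  if (length(s) == 0L) return(TRUE)
  if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
    return("all genesets must be named")
  if (anyDuplicated(names(s))) return("geneset names must be unique")
  if (!all(vapply(s, is.character, logical(1))))
    return("genesets must be character vectors")
  if (any(lengths(s) == 0L)) return("empty genesets are not allowed")
  if (length(object@provenance) != length(s))
    return("provenance must have one entry per set")
  TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets Named list of character vectors; duplicate genes within a set
#'   are collapsed.
#' @param provenance Single label or one label per set.
#' @return A [GeneSetCollection-class] object.
#' @export
GeneSetCollection <- function(sets = list(), provenance = "custom") {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (length(provenance) == 1L) provenance <- rep(provenance, length(sets))
  new("GeneSetCollection", sets = sets, provenance = provenance)
}

#' @describeIn GeneSetCollection-class Names of the genesets.
#' @param x,object A `GeneSetCollection`.
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' Extract the list of genesets
#'
#' @param x A [GeneSetCollection-class].
#' @return Named list of character vectors.
#' @export
geneSets <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  x@sets
}

#' Provenance labels of a collection
#' @param x A [GeneSetCollection-class].
#' @return Character vector parallel to [geneSets()].
#' @export
setProvenance <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  setNames(x@provenance, names(x@sets))
}

#' @describeIn GeneSetCollection-class Number of genesets.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class Extract one geneset by name or index.
#' @param i Set name or index.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "set(s)\n")
  if (length(object@sets)) {
    n <- head(names(object@sets), 5L)
    cat("  sizes:", paste0(n, "=", lengths(object@sets)[n], collapse = ", "),
        if (length(object@sets) > 5L) "..." else "", "\n")
    cat("  provenance:", paste(unique(object@provenance), collapse = ", "),
        "\n")
  }
})

#' Cell-line panel: expression, metadata, drug response, proteomics
#'
#' Container for a cell-line pharmacogenomic panel. Expression is a
#' gene-by-line log-scale matrix; `lineMeta` carries the cancer-type label and
#' lineage flags; `auc` is a long-format drug-response table with columns
#' `cell_line`, `compound`, `auc` (values in \[0,1\], `NA` = not tested) and
#' optionally `source`; `protein` is an optional protein-channel-by-line
#' abundance matrix.
#'
#' @slot expr Gene-by-cell-line numeric matrix.
#' @slot lineMeta data.frame with columns `cell_line`, `cancer_type`,
#'   `lineage` (e.g. "Engineered", "Fibroblast" flag decoys).
#' @slot auc data.frame drug-response table (may have zero rows).
#' @slot protein Optional numeric matrix (protein channels x lines) or NULL.
#' @export
setClass("CellLinePanel",
  representation(expr = "matrix", lineMeta = "data.frame",
                 auc = "data.frame", protein = "matrixOrNULL"))

setValidity("CellLinePanel", function(object) {
  m <- object@lineMeta
  need <- c("cell_line", "cancer_type", "lineage")
  if (!all(need %in% names(m)))
    return(paste("lineMeta must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$cell_line)) return("duplicate cell-line ids")
  if (!all(colnames(object@expr) %in% m$cell_line))
    return("expression columns missing from lineMeta")
  a <- object@auc
  if (nrow(a)) {
    if (!all(c("cell_line", "compound", "auc") %in% names(a)))
      return("auc table needs cell_line, compound, auc columns")
    v <- a$auc[!is.na(a$auc)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      return("AUC values must lie in [0,1]")
    if (!all(a$cell_line %in% m$cell_line))
      return("auc table references unknown cell lines")
  }
  if (!is.null(object@protein) &&
      !all(colnames(object@protein) %in% m$cell_line))
    return("protein columns missing from lineMeta")
  TRUE
})

#' Construct a CellLinePanel
#'
#' @param expr Gene-by-line numeric matrix with dimnames.
#' @param lineMeta data.frame with `cell_line`, `cancer_type`, `lineage`.
#' @param auc Long drug-response data.frame (`cell_line`, `compound`, `auc`).
#' @param protein Optional protein-by-line matrix.
#' @return A [CellLinePanel-class].
#' @export
CellLinePanel <- function(expr, lineMeta,
                          auc = data.frame(cell_line = character(),
                                           compound = character(),
                                           auc = numeric()),
                          protein = NULL) {
  lineMeta$cell_line <- as.character(lineMeta$cell_line)
  new("CellLinePanel", expr = expr, lineMeta = lineMeta,
      auc = auc, protein = protein)
}

#' @describeIn CellLinePanel-class Cell-line metadata accessor.
#' @param x,object A `CellLinePanel`.
#' @export
lineMeta <- function(x) { stopifnot(is(x, "CellLinePanel")); x@lineMeta }

#' @describeIn CellLinePanel-class Expression matrix accessor.
#' @export
panelExpr <- function(x) { stopifnot(is(x, "CellLinePanel")); x@expr }

#' @describeIn CellLinePanel-class Drug-response table accessor.
#' @export
drugAuc <- function(x) { stopifnot(is(x, "CellLinePanel")); x@auc }

#' @describeIn CellLinePanel-class Protein abundance matrix (or NULL).
#' @export
proteinAbundance <- function(x) { stopifnot(is(x, "CellLinePanel")); x@protein }

setMethod("show", "CellLinePanel", function(object) {
  cat("CellLinePanel:", ncol(object@expr), "cell lines,",
      nrow(object@expr), "genes,",
      length(unique(object@lineMeta$cancer_type)), "cancer types\n")
  cat("  drug records:", nrow(object@auc),
      "| protein channels:",
      if (is.null(object@protein)) 0L else nrow(object@protein), "\n")
})

#' Specification of a synthetic multi-cancer study
#'
#' Describes the planted statistical structure of a synthetic cohort and
#' cell-line panel: per-cancer-type sample sizes, gene modules with target
#' Spearman correlations to the query gene (optionally differing by mutation
#' stratum), mutation fractions, a proportional-hazards survival link, a drug
#' panel with target expression-AUC correlations, and an mRNA-protein noise
#' level.
#'
#' @slot cancerTypes data.frame with columns `acronym`, `n_samples`,
#'   `mut_fraction`, `log_hr` (log hazard ratio of high-vs-low query
#'   expression), `baseline_rate`, `censor_rate`.
#' @slot nGenes Total number of genes (modules carved from the front).
#' @slot queryGene Query gene symbol.
#' @slot modules List of module descriptors: each a list with `name`, `size`,
#'   and `rho` — either a single numeric, a per-cancer-type named vector, or a
#'   list with `WT`/`MUT` entries for stratum-specific targets.
#' @slot drugPanel data.frame with `compound` and `slope` (sign controls the
#'   planted expression-AUC correlation), or per-type columns.
#' @slot proteinCor Target Pearson correlation between query mRNA and protein.
#' @slot seed Integer master seed.
#' @export
setClass("SyntheticSpec",
  representation(cancerTypes = "data.frame", nGenes = "numeric",
                 queryGene = "character", modules = "list",
                 drugPanel = "data.frame", proteinCor = "numeric",
                 seed = "numeric"))

setValidity("SyntheticSpec", function(object) {
  ct <- object@cancerTypes
  if (!all(c("acronym", "n_samples") %in% names(ct)))
    return("cancerTypes needs acronym and n_samples")
  if (any(ct$n_samples < 4)) return("n_samples must be >= 4")
  if (any(ct$mut_fraction < 0 | ct$mut_fraction > 1))
    return("mut_fraction must lie in [0,1]")
  if (any(ct$censor_rate < 0 | ct$censor_rate >= 1))
    return("censor_rate must lie in [0,1)")
  for (m in object@modules) {
    r <- unlist(m$rho)
    if (any(abs(r) >= 1)) return(sprintf(
      "module '%s': target rho must lie in (-1,1)", m$name))
  }
  if (sum(vapply(object@modules, function(m) m$size, numeric(1))) >
      object@nGenes - 1)
    return("modules exceed the gene budget (query gene reserved)")
  TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", nrow(object@cancerTypes), "cancer types,",
      object@nGenes, "genes, query =", object@queryGene, "\n")
  cat("  modules:", paste(vapply(object@modules, `[[`, character(1), "name"),
                          collapse = ", "), "\n")
  cat("  seed:", object@seed, "\n")
})

#' Result of consensus K-means clustering
#'
#' @slot consensus List (by k) of symmetric consensus matrices with unit
#'   diagonal, entries = empirical co-clustering frequencies in \[0,1\].
#' @slot area Numeric vector of consensus CDF areas, one per k.
#' @slot deltaArea Numeric vector: raw area at the smallest k, then relative
#'   successive increases.
#' @slot chosenK Selected number of clusters (NA when degenerate).
#' @slot assignments Named integer vector of cluster labels at `chosenK`
#'   (empty when degenerate).
#' @slot degenerate Logical flag (e.g. all items identical).
#' @export
setClass("ConsensusResult",
  representation(consensus = "list", area = "numeric", deltaArea = "numeric",
                 chosenK = "numeric", assignments = "numeric",
                 degenerate = "logical"))

setValidity("ConsensusResult", function(object) {
  for (M in object@consensus) {
    if (!isSymmetric(unname(M), tol = 1e-8)) return("consensus not symmetric")
    if (any(M < -1e-9 | M > 1 + 1e-9)) return("consensus entries outside [0,1]")
    if (any(abs(diag(M) - 1) > 1e-9)) return("consensus diagonal must be 1")
  }
  TRUE
})

#' @describeIn ConsensusResult-class Chosen number of clusters.
#' @param x,object A `ConsensusResult`.
#' @export
chosenK <- function(x) { stopifnot(is(x, "ConsensusResult")); x@chosenK }

#' @describeIn ConsensusResult-class Cluster assignments at the chosen k.
#' @export
clusterAssignments <- function(x) {
  stopifnot(is(x, "ConsensusResult")); x@assignments
}

#' @describeIn ConsensusResult-class Consensus matrix for a given k.
#' @param k Number of clusters.
#' @export
consensusMatrix <- function(x, k) {
  stopifnot(is(x, "ConsensusResult"))
  x@consensus[[as.character(k)]]
}

#' @describeIn ConsensusResult-class Delta-area sequence used for k selection.
#' @export
deltaArea <- function(x) { stopifnot(is(x, "ConsensusResult")); x@deltaArea }

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult over k =",
      paste(names(object@consensus), collapse = ","), "\n")
  if (object@degenerate) cat("  degenerate input; no k chosen\n")
  else cat("  chosen k:", object@chosenK, "\n")
})
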
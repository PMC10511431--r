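#' Read a gene-by-sample expression matrix from TSV
#'
#' Reads a tab-separated expression table in either the cohort dialect (genes
#' in rows, one header row of sample ids) or the cell-line dialect (samples in
#' rows, one header row of gene ids). Empty or non-numeric cells become `NA`
#' (the missing-value mask). Duplicate gene symbols are resolved by keeping
#' the row with the highest mean expression; duplicate sample ids are an
#' error.
#'
#' @param path Path to the TSV file.
#' @param orientation `"genes_in_rows"` (default, TCGA PanCanAtlas dialect) or
#'   `"samples_in_rows"` (CCLE dialect); the result is always gene-by-sample.
#' @return Numeric matrix, genes in rows, samples in columns, `NA` for masked
#'   cells. Log-scale values (log10(x+1) convention) are expected but not
#'   enforced beyond non-negativity of finite entries.
#' @export
readExpressionMatrix <- function(path,
                                 orientation = c("genes_in_rows",
                                                 "samples_in_rows")) {
  orientation <- match.arg(orientation)
  first <- readLines(path, n = 1L)
  if (!length(first) || !grepl("\t", first))
    stop("malformed header at line 1 of '", path, "': no tab separator")
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  mat <- vapply(body, function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(body)))
  if (nrow(body) == 1L) mat <- matrix(mat, nrow = 1L,
                                      dimnames = list(NULL, names(body)))
  rownames(mat) <- ids
  if (orientation == "samples_in_rows") mat <- t(mat)
  mat <- dedupeGenes(mat)
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]),
               collapse = ", "))
  validateExpressionMatrix(mat)
  mat
}

# keep, per duplicated symbol, the row with highest mean expression
dedupeGenes <- function(mat) {
  if (!anyDuplicated(rownames(mat))) return(mat)
  means <- rowMeans(mat, na.rm = TRUE)
  ord <- order(rownames(mat), -means)
  keep <- ord[!duplicated(rownames(mat)[ord])]
  mat[sort(keep), , drop = FALSE]
}

#' Validate the expression-matrix contract
#'
#' Checks the invariants of the shared expression container: unique gene and
#' sample identifiers, and non-negative finite values under the log10(x+1)
#' convention.
#'
#' @param mat Gene-by-sample numeric matrix.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validateExpressionMatrix <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must carry gene and sample identifiers")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]),
               collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample ids")
  v <- mat[is.finite(mat)]
  if (length(v) && min(v) < 0)
    stop("negative values are inconsistent with the log10(x+1) convention")
  invisible(TRUE)
}

#' Write an expression matrix as TSV
#'
#' Emits the same dialects [readExpressionMatrix()] consumes: tab separators,
#' LF line endings, no quoting, `NA` cells written empty.
#'
#' @inheritParams readExpressionMatrix
#' @param mat Gene-by-sample numeric matrix.
#' @param idColumn Header of the identifier column.
#' @return Invisibly, `path`.
#' @export
writeExpressionMatrix <- function(mat, path,
                                  orientation = c("genes_in_rows",
                                                  "samples_in_rows"),
                                  idColumn = "gene_id") {
  orientation <- match.arg(orientation)
  out <- if (orientation == "genes_in_rows") mat else t(mat)
  df <- data.frame(id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", eol = "\n")
  invisible(path)
}

#' Read / write a per-sample clinical annotation table
#'
#' Tab-separated table with one row per sample. Recognised columns:
#' `sample_id`, `cancer_type`, `tp53_status`, `tp53_class`, `os_time`,
#' `os_event`, `size_stage`, `node_stage`, `met_stage`, plus any covariate
#' expression columns. Enforces: `os_time` missing implies `os_event` missing,
#' and `tp53_class == "WT"` iff `tp53_status == "WT"` where both are known.
#'
#' @param path File path.
#' @return data.frame of sample annotations.
#' @export
readSampleAnnotation <- function(path) {
  ann <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(ann)) stop("annotation table needs sample_id")
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample ids in annotation")
  if ("os_event" %in% names(ann)) ann$os_event <- as.logical(ann$os_event)
  validateAnnotation(ann)
  ann
}

validateAnnotation <- function(ann) {
  if (all(c("os_time", "os_event") %in% names(ann))) {
    bad <- is.na(ann$os_time) & !is.na(ann$os_event)
    if (any(bad)) stop("os_event present without os_time for ",
                       sum(bad), " sample(s)")
    if (any(ann$os_time < 0, na.rm = TRUE)) stop("negative survival times")
  }
  if (all(c("tp53_status", "tp53_class") %in% names(ann))) {
    known <- !is.na(ann$tp53_class) & ann$tp53_class != "Unknown" &
      !is.na(ann$tp53_status)
    bad <- known & ((ann$tp53_class == "WT") != (ann$tp53_status == "WT"))
    if (any(bad)) stop("tp53_class/tp53_status inconsistent for ",
                       sum(bad), " sample(s)")
  }
  invisible(TRUE)
}

#' @rdname readSampleAnnotation
#' @param ann Annotation data.frame.
#' @export
writeSampleAnnotation <- function(ann, path) {
  validateAnnotation(ann)
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n")
  invisible(path)
}

#' Bundle expression and annotations into a cohort object
#'
#' Builds a [SummarizedExperiment::SummarizedExperiment] with assay `exprs`
#' and the annotation table as column data, aligned on sample id.
#'
#' @param expr Gene-by-sample matrix.
#' @param ann Sample annotation data.frame with `sample_id`.
#' @return A `SummarizedExperiment`.
#' @export
queryCohort <- function(expr, ann) {
  validateExpressionMatrix(expr)
  validateAnnotation(ann)
  if (!all(colnames(expr) %in% ann$sample_id))
    stop("annotation missing for some samples")
  ann <- ann[match(colnames(expr), ann$sample_id), , drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = expr),
    colData = S4Vectors::DataFrame(ann, row.names = ann$sample_id))
}

# canonical variant-class vocabulary
.tp53Truncating <- c("nonsense", "frameshift", "splice")
.tp53Inframe    <- c("missense", "inframe indel")
.tp53Known      <- c(.tp53Truncating, .tp53Inframe, "silent", "none")

#' Classify per-sample TP53 functional status
#'
#' Collapses per-sample variant calls and a copy-number call into a mutation
#' status (WT/MUT) and a functional class. Any non-silent variant or a
#' homozygous deletion makes a sample MUT. Classes: nonsense, frameshift and
#' splice variants and homozygous deletion give `TruncatingHomDel`; missense
#' and inframe indels give `InframeMissense`; silent-only or no alteration
#' gives `WT`. Mixed alterations resolve by severity precedence
#' `TruncatingHomDel > InframeMissense`. The class map is configurable so
#' alternative functional groupings can be declared.
#'
#' @param mutationRecords List, one element per sample, each a character
#'   vector of variant-class strings (may be empty or `"none"`).
#' @param cnaRecords Character vector per sample, one of
#'   `"homozygous deletion"`, `"other"`, `"none"`.
#' @param classMap Named character vector mapping variant classes to
#'   `"TruncatingHomDel"`, `"InframeMissense"` or `"WT"`.
#' @return data.frame with columns `tp53_status` and `tp53_class`, one row per
#'   sample, preserving `names(mutationRecords)` when present.
#' @export
classifyTP53 <- function(mutationRecords, cnaRecords,
                         classMap = c(nonsense = "TruncatingHomDel",
                                      frameshift = "TruncatingHomDel",
                                      splice = "TruncatingHomDel",
                                      missense = "InframeMissense",
                                      `inframe indel` = "InframeMissense",
                                      silent = "WT",
                                      none = "WT")) {
  stopifnot(length(mutationRecords) == length(cnaRecords))
  badCna <- !cnaRecords %in% c("homozygous deletion", "other", "none")
  if (any(badCna)) stop("unknown CNA call: ",
                        paste(unique(cnaRecords[badCna]), collapse = ", "))
  res <- t(vapply(seq_along(mutationRecords), function(i) {
    vars <- mutationRecords[[i]]
    vars <- vars[!is.na(vars) & vars != ""]
    unknown <- setdiff(vars, names(classMap))
    if (length(unknown)) stop("unknown variant class: ",
                              paste(unknown, collapse = ", "))
    classes <- unname(classMap[vars])
    if (cnaRecords[i] == "homozygous deletion")
      classes <- c(classes, "TruncatingHomDel")
    if ("TruncatingHomDel" %in% classes) c("MUT", "TruncatingHomDel")
    else if ("InframeMissense" %in% classes) c("MUT", "InframeMissense")
    else c("WT", "WT")
  }, character(2)))
  data.frame(tp53_status = res[, 1L], tp53_class = res[, 2L],
             row.names = names(mutationRecords), stringsAsFactors = FALSE)
}

#' Read a GMT geneset file
#'
#' Standard GMT: one set per line, fields `name`, `description`, then one or
#' more gene symbols, tab-separated. Duplicate genes within a line are
#' collapsed; a duplicate set name or a line with fewer than three fields is
#' an error.
#'
#' @param path Path to the GMT file.
#' @param provenance Provenance label attached to every set.
#' @return A [GeneSetCollection-class].
#' @export
readGmt <- function(path, provenance = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    nm <- f[[1L]]
    if (nm %in% names(sets)) stop("duplicate geneset name: ", nm)
    sets[[nm]] <- unique(f[-(1:2)])
  }
  GeneSetCollection(sets, provenance)
}

#' Write a GeneSetCollection as GMT
#'
#' @param collection A [GeneSetCollection-class].
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions (defaults to
#'   the provenance labels).
#' @return Invisibly, `path`.
#' @export
writeGmt <- function(collection, path, descriptions = NULL) {
  sets <- geneSets(collection)
  if (is.null(descriptions)) descriptions <- collection@provenance
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Build a knock-out signature from a differential-expression table
#'
#' Constructs two genesets from a DE result: the top `n` upregulated genes
#' (largest effect size) and the top `n` downregulated genes (most negative),
#' among genes passing an adjusted-significance filter. The sets are disjoint
#' by construction.
#'
#' @param deTable data.frame with at least a gene column and an effect-size
#'   column (e.g. log2 fold change); an adjusted-p column is used when the
#'   significance filter is active.
#' @param n Genes per set (default 100).
#' @param geneCol,effectCol,padjCol Column names.
#' @param padjMax Significance filter; set `Inf` to rank all genes.
#' @param upName,downName Names of the emitted sets.
#' @return A [GeneSetCollection-class] with the UP and DOWN sets.
#' @export
buildKoSignature <- function(deTable, n = 100, geneCol = "gene",
                             effectCol = "log2fc", padjCol = "padj",
                             padjMax = 0.05,
                             upName = "KO_UP", downName = "KO_DOWN") {
  stopifnot(all(c(geneCol, effectCol) %in% names(deTable)))
  tab <- deTable[!is.na(deTable[[effectCol]]), , drop = FALSE]
  if (is.finite(padjMax)) {
    if (!padjCol %in% names(tab)) stop("missing significance column: ", padjCol)
    tab <- tab[!is.na(tab[[padjCol]]) & tab[[padjCol]] < padjMax, ,
               drop = FALSE]
  }
  eff <- tab[[effectCol]]
  nUp <- sum(eff > 0); nDown <- sum(eff < 0)
  if (nUp < n) stop("only ", nUp, " upregulated genes available, need ", n)
  if (nDown < n) stop("only ", nDown, " downregulated genes available, need ",
                      n)
  up <- tab[[geneCol]][order(-eff)][seq_len(n)]
  down <- tab[[geneCol]][order(eff)][seq_len(n)]
  sets <- list(up, down)
  names(sets) <- c(upName, downName)
  GeneSetCollection(sets, provenance = "ko_signature")
}

#' Intersect a gene set with an external reference list
#'
#' Exact, case-sensitive symbol intersection with order-stable output (the
#' order of `genes` is preserved).
#'
#' @param genes Character vector.
#' @param reference Character vector (e.g. a co-expression list obtained
#'   offline from an external resource).
#' @return List with `overlap` (character vector) and `count`.
#' @export
overlapWithReference <- function(genes, reference) {
  ov <- genes[genes %in% reference]
  ov <- ov[!duplicated(ov)]
  list(overlap = ov, count = length(ov))
}
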
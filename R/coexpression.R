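#' Filter genes by per-cancer-type expression level and variability
#'
#' A gene is retained iff, in at least one cancer type, its mean expression
#' strictly exceeds `meanThresh` and its sample standard deviation strictly
#' exceeds `sdThresh`. The query gene is force-retained (with a warning) even
#' when it fails the filter, since every downstream stage needs it.
#'
#' @param expr Gene-by-sample matrix (log scale).
#' @param groups Named character vector mapping sample id to cancer type, or a
#'   vector aligned with `colnames(expr)`.
#' @param meanThresh,sdThresh Strict thresholds (defaults 0.5 and 0.2).
#' @param queryGene Optional query gene symbol to force-retain.
#' @return Character vector of retained gene ids.
#' @export
filterGenes <- function(expr, groups, meanThresh = 0.5, sdThresh = 0.2,
                        queryGene = NULL) {
  if (length(groups) == 0 || all(is.na(groups))) stop("empty sample grouping")
  if (!is.null(names(groups))) groups <- groups[colnames(expr)]
  stopifnot(length(groups) == ncol(expr))
  keep <- rep(FALSE, nrow(expr))
  for (g in unique(groups[!is.na(groups)])) {
    sub <- expr[, which(groups == g), drop = FALSE]
    if (ncol(sub) < 2L) next
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1L, sd, na.rm = TRUE)
    keep <- keep | (mu > meanThresh & sdv > sdThresh & !is.na(sdv))
  }
  out <- rownames(expr)[keep]
  if (!is.null(queryGene) && !queryGene %in% out) {
    if (!queryGene %in% rownames(expr))
      stop("query gene '", queryGene, "' absent from matrix")
    warning("query gene '", queryGene,
            "' failed the expression filter; force-retained")
    out <- c(queryGene, out)
  }
  out
}

# Spearman p-value: exact permutation distribution (AS89 via cor.test) for
# n <= 10 without ties, t approximation otherwise
spearmanP <- function(rho, n, x = NULL, y = NULL) {
  if (is.na(rho) || n < 3L) return(NA_real_)
  if (n <= 10L && !is.null(x)) {
    p <- tryCatch(
      suppressWarnings(cor.test(x, y, method = "spearman",
                                exact = TRUE)$p.value),
      error = function(e) NA_real_)
    if (!is.na(p)) return(min(p, 1))
  }
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tval), df = n - 2)
}

#' Spearman co-expression profile of the query gene in one context
#'
#' Correlates the query gene with every other gene over the given samples
#' using Spearman's rank correlation (average ranks for ties), on
#' pairwise-complete observations. Two-sided p-values use the exact
#' permutation distribution for n <= 10 and the t approximation otherwise;
#' q-values are Benjamini-Hochberg within the context (genes with undefined
#' rho — zero variance or fewer than 3 complete pairs — are excluded from the
#' BH family). The query gene itself is excluded from the output.
#'
#' @param expr Gene-by-sample matrix.
#' @param queryGene Query gene symbol (must be a row of `expr`).
#' @param samples Sample ids defining the context (default: all).
#' @param context Label stored on the result (e.g. `"BRCA:ALL"`).
#' @return data.frame with columns `gene`, `rho`, `p`, `q`, `n_pairs` and a
#'   `context` attribute.
#' @export
spearmanProfile <- function(expr, queryGene, samples = colnames(expr),
                            context = "ALL") {
  if (!queryGene %in% rownames(expr))
    stop("query gene '", queryGene, "' absent from matrix")
  sub <- expr[, samples, drop = FALSE]
  qv <- sub[queryGene, ]
  if (sum(!is.na(qv)) < 3L)
    stop("context has fewer than 3 samples with observed query values")
  others <- setdiff(rownames(sub), queryGene)
  mat <- sub[others, , drop = FALSE]

  rho <- rep(NA_real_, length(others))
  p <- rep(NA_real_, length(others))
  np <- integer(length(others))
  names(rho) <- names(p) <- names(np) <- others

  completeGene <- !apply(is.na(mat), 1L, any)
  qComplete <- !anyNA(qv)
  if (qComplete && any(completeGene)) {
    idx <- which(completeGene)
    n <- ncol(mat)
    qr <- rank(qv)
    rmat <- t(apply(mat[idx, , drop = FALSE], 1L, rank))
    sds <- apply(rmat, 1L, sd)
    ok <- sds > 0 & sd(qr) > 0
    rr <- suppressWarnings(as.numeric(cor(qr, t(rmat))))
    rr[!ok] <- NA_real_
    rho[idx] <- rr
    np[idx] <- n
    if (n > 10L) {
      tv <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
      p[idx] <- pmin(2 * pt(-abs(tv), df = n - 2), 1)
      p[idx][abs(rr) >= 1 & !is.na(rr)] <- 0
    } else {
      for (i in idx) p[i] <- spearmanP(rho[i], n, mat[i, ], qv)
    }
    slow <- setdiff(which(!completeGene), idx)
  } else slow <- seq_along(others)

  for (i in slow) {
    x <- mat[i, ]
    okp <- !is.na(x) & !is.na(qv)
    np[i] <- sum(okp)
    if (np[i] < 3L) next
    xs <- x[okp]; ys <- qv[okp]
    if (sd(xs) == 0 || sd(ys) == 0) next
    rho[i] <- suppressWarnings(cor(xs, ys, method = "spearman"))
    p[i] <- spearmanP(rho[i], np[i], xs, ys)
  }

  q <- rep(NA_real_, length(others))
  inFam <- !is.na(p)
  q[inFam] <- p.adjust(p[inFam], method = "BH")
  out <- data.frame(gene = others, rho = unname(rho), p = unname(p),
                    q = unname(q), n_pairs = unname(np),
                    stringsAsFactors = FALSE)
  attr(out, "context") <- context
  out
}

#' Genes passing the correlation screen in one profile
#'
#' @param profile Output of [spearmanProfile()].
#' @param threshold Absolute Spearman rho cutoff (default 0.6).
#' @param requireQ Optional BH q cutoff additionally required (default `NULL`,
#'   threshold-only screen).
#' @return List with `positive` and `negative` gene vectors and `counts`.
#' @export
significantGenes <- function(profile, threshold = 0.6, requireQ = NULL) {
  ok <- !is.na(profile$rho)
  if (!is.null(requireQ)) ok <- ok & !is.na(profile$q) & profile$q < requireQ
  pos <- profile$gene[ok & profile$rho >= threshold]
  neg <- profile$gene[ok & profile$rho <= -threshold]
  list(positive = pos, negative = neg,
       counts = c(positive = length(pos), negative = length(neg),
                  total = length(pos) + length(neg)))
}

#' Union of screen-passing genes across cancer types
#'
#' Collects every gene passing the correlation screen in at least one
#' per-cancer profile and assembles the gene-by-cancer rho matrix used for
#' heatmaps and for consensus clustering of cancer types.
#'
#' @param profiles Named list of [spearmanProfile()] outputs, one per cancer
#'   type.
#' @param threshold Absolute rho cutoff (default 0.6).
#' @param requireQ Optional additional q cutoff.
#' @return List with `genes` (character vector) and `rhoMatrix`
#'   (gene x cancer type).
#' @export
unionCorrelatedGenes <- function(profiles, threshold = 0.6, requireQ = NULL) {
  stopifnot(length(names(profiles)) == length(profiles))
  sig <- lapply(profiles, function(p) {
    s <- significantGenes(p, threshold, requireQ)
    c(s$positive, s$negative)
  })
  genes <- sort(unique(unlist(sig)))
  rhoMatrix <- matrix(NA_real_, length(genes), length(profiles),
                      dimnames = list(genes, names(profiles)))
  for (ct in names(profiles)) {
    p <- profiles[[ct]]
    idx <- match(genes, p$gene)
    rhoMatrix[, ct] <- p$rho[idx]
  }
  list(genes = genes, rhoMatrix = rhoMatrix)
}

#' Do per-cancer screen counts track query expression level?
#'
#' Correlates the numbers of screen-passing genes (total, positive, negative)
#' against the mean query-gene expression across cancer types, to test
#' whether apparent network involvement merely reflects expression level.
#'
#' @param counts data.frame with columns `cancer_type`, `total`, `positive`,
#'   `negative` (as produced from [significantGenes()] counts).
#' @param meanExpr Named numeric vector of mean query expression per cancer
#'   type.
#' @param method Correlation method (default Spearman).
#' @return Named numeric vector of correlations (`total`, `positive`,
#'   `negative`); `NA` where a count vector has zero variance.
#' @export
countsVsLevel <- function(counts, meanExpr, method = "spearman") {
  ok <- counts$cancer_type %in% names(meanExpr)
  counts <- counts[ok, , drop = FALSE]
  if (nrow(counts) < 3L) stop("need at least 3 cancer types")
  x <- meanExpr[counts$cancer_type]
  corOne <- function(y) {
    if (sd(y) == 0 || sd(x) == 0) return(NA_real_)
    suppressWarnings(cor(x, y, method = method))
  }
  c(total = corOne(counts$total), positive = corOne(counts$positive),
    negative = corOne(counts$negative))
}
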
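#' Correlate a per-context association profile with hazard ratios
#'
#' Second-order analysis: for every gene (or geneset), the vector of its
#' per-cancer-type association values (Spearman rho with the query gene, or
#' NES) is correlated with the vector of per-cancer-type univariate hazard
#' ratios, over pairwise-complete contexts. Units with fewer than
#' `minContexts` complete pairs are excluded and counted.
#'
#' @param valueMatrix Unit-by-context numeric matrix (genes x cancer types of
#'   rho, or genesets x cancer types of NES); `NA` allowed.
#' @param hrVector Named numeric vector of per-context hazard ratios (used as
#'   printed; set `logHr = TRUE` to correlate against log HR).
#' @param minContexts Minimum complete pairs (default 3).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param logHr Correlate against log(HR) instead of HR.
#' @param breaks Histogram break points for the r2 distribution.
#' @return List: `results` (data.frame `unit`, `r2`, `n_contexts`),
#'   `histogram` (a `hist`-style list), `nAbove` / `nBelow` (counts with
#'   r2 > 0.5 / < -0.5), `nExcluded`.
#' @export
correlationVsHazard <- function(valueMatrix, hrVector, minContexts = 3,
                                method = c("spearman", "pearson"),
                                logHr = FALSE,
                                breaks = seq(-1, 1, by = 0.1)) {
  method <- match.arg(method)
  shared <- intersect(colnames(valueMatrix), names(hrVector))
  if (length(shared) < minContexts)
    stop("fewer than ", minContexts, " contexts with both values")
  vm <- valueMatrix[, shared, drop = FALSE]
  hr <- hrVector[shared]
  if (logHr) hr <- log(hr)
  r2 <- rep(NA_real_, nrow(vm))
  nCtx <- integer(nrow(vm))
  for (i in seq_len(nrow(vm))) {
    ok <- !is.na(vm[i, ]) & !is.na(hr)
    nCtx[i] <- sum(ok)
    if (nCtx[i] < minContexts) next
    x <- vm[i, ok]; y <- hr[ok]
    if (sd(x) == 0 || sd(y) == 0) next  # zero variance: r2 stays missing
    r2[i] <- suppressWarnings(cor(x, y, method = method))
  }
  keep <- nCtx >= minContexts
  results <- data.frame(unit = rownames(vm)[keep], r2 = r2[keep],
                        n_contexts = nCtx[keep], stringsAsFactors = FALSE)
  obs <- results$r2[!is.na(results$r2)]
  h <- if (length(obs)) graphics::hist(obs, breaks = breaks, plot = FALSE)
       else NULL
  list(results = results, histogram = h,
       nAbove = sum(obs > 0.5), nBelow = sum(obs < -0.5),
       nExcluded = sum(!keep))
}

#' @rdname correlationVsHazard
#' @param nesMatrix Geneset-by-context NES matrix.
#' @export
nesVsHazard <- function(nesMatrix, hrVector, minContexts = 3,
                        method = c("spearman", "pearson"), logHr = FALSE,
                        breaks = seq(-1, 1, by = 0.1)) {
  correlationVsHazard(nesMatrix, hrVector, minContexts, method, logHr, breaks)
}

# k-means++ seeding followed by Lloyd iterations; best of `nstart` restarts
kmeansPP <- function(x, k, nstart = 10, iterMax = 300) {
  n <- nrow(x)
  # k = n has the trivial exact optimum: every item its own cluster
  if (k >= n) return(list(cluster = seq_len(n), tot.withinss = 0))
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1L, ] <- x[sample.int(n, 1L), ]
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    if (k > 1L) for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1L, prob = prob), ]
      d2 <- pmin(d2, rowSums(
        (x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
    }
    centers <- centers[!duplicated(centers), , drop = FALSE]
    fit <- suppressWarnings(
      kmeans(x, centers = centers, iter.max = iterMax))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Consensus K-means clustering of cancer types
#'
#' Stability-based clustering of items (cancer types) by their correlation
#' profiles: for each candidate k, items are repeatedly subsampled and
#' clustered with K-means (Euclidean distance, k-means++ initialisation, 10
#' restarts), and co-clustering frequencies among co-sampled pairs are
#' accumulated into a consensus matrix. The consensus CDF area is computed
#' per k; the delta-area sequence is the raw area at the smallest k followed
#' by relative successive increases. The chosen k reads the elbow of the
#' delta-area plot: among the k whose delta-area exceeds `elbowThreshold`,
#' the k with the largest drop to the next delta-area value (`kSelection =
#' "elbow"`, default). `kSelection = "threshold"` instead takes the largest
#' k whose delta-area exceeds the threshold; note that with a K-means inner
#' loop every crisp split of a clean cluster raises the CDF area by the
#' fraction of broken pairs, so on well-separated data that variant tends to
#' run to the top of the k range (see the methods vignette). Final
#' assignments come from average-linkage hierarchical clustering of the
#' chosen consensus matrix.
#'
#' @param profileMatrix Item-by-feature numeric matrix (cancer types x genes
#'   of rho values); `NA` entries are replaced by 0 (no association evidence).
#' @param kRange Candidate cluster counts (default 2:10, truncated to the
#'   item count minus one).
#' @param reps Subsampling repetitions per k (default 1000).
#' @param subsample Item subsampling proportion (default 0.8).
#' @param seed Integer seed.
#' @param elbowThreshold Minimum relative area increase for a k to be
#'   considered (default 0.025).
#' @param kSelection `"elbow"` (maximal delta-area drop) or `"threshold"`
#'   (largest k above the threshold).
#' @param nstart,iterMax K-means restarts and iteration cap.
#' @return A [ConsensusResult-class].
#' @export
consensusCluster <- function(profileMatrix, kRange = 2:10, reps = 1000,
                             subsample = 0.8, seed = 7,
                             elbowThreshold = 0.025,
                             kSelection = c("elbow", "threshold"),
                             nstart = 10, iterMax = 300) {
  kSelection <- match.arg(kSelection)
  x <- as.matrix(profileMatrix)
  x[is.na(x)] <- 0
  n <- nrow(x)
  if (max(kRange) + 1 > n)
    stop("k range exceeds item count: max k ", max(kRange),
         " needs at least ", max(kRange) + 1, " items, have ", n)
  itemNames <- rownames(x) %||% as.character(seq_len(n))
  if (max(dist(x)) == 0) {
    return(new("ConsensusResult", consensus = list(),
               area = numeric(), deltaArea = numeric(),
               chosenK = NA_real_, assignments = numeric(),
               degenerate = TRUE))
  }
  set.seed(seed)
  m <- max(2L, floor(subsample * n))
  consensus <- list()
  area <- numeric(length(kRange))
  for (ki in seq_along(kRange)) {
    k <- kRange[ki]
    together <- matrix(0, n, n)
    cosampled <- matrix(0, n, n)
    for (b in seq_len(reps)) {
      idx <- sample.int(n, m)
      fit <- kmeansPP(x[idx, , drop = FALSE], min(k, m), nstart, iterMax)
      lab <- fit$cluster
      same <- outer(lab, lab, `==`) * 1
      cosampled[idx, idx] <- cosampled[idx, idx] + 1
      together[idx, idx] <- together[idx, idx] + same
    }
    M <- ifelse(cosampled > 0, together / pmax(cosampled, 1), 0)
    diag(M) <- 1
    M <- (M + t(M)) / 2
    dimnames(M) <- list(itemNames, itemNames)
    consensus[[as.character(k)]] <- M
    vals <- M[upper.tri(M)]
    # \int_0^1 CDF(x) dx = 1 - mean(X) for X supported on [0,1]
    area[ki] <- 1 - mean(vals)
  }
  deltaA <- numeric(length(kRange))
  deltaA[1L] <- area[1L]
  if (length(kRange) > 1L)
    for (ki in 2:length(kRange))
      deltaA[ki] <- (area[ki] - area[ki - 1L]) / area[ki - 1L]
  names(area) <- names(deltaA) <- as.character(kRange)
  pass <- which(deltaA > elbowThreshold)
  chosen <- if (!length(pass)) {
    kRange[1L]
  } else if (kSelection == "threshold") {
    kRange[max(pass)]
  } else {
    # elbow: the considered k after which the delta-area curve flattens most
    nxt <- c(deltaA[-1L], 0)
    drop <- deltaA - nxt
    kRange[pass[which.max(drop[pass])]]
  }
  Mc <- consensus[[as.character(chosen)]]
  hc <- stats::hclust(stats::as.dist(1 - Mc), method = "average")
  assign <- stats::cutree(hc, k = chosen)
  names(assign) <- itemNames
  new("ConsensusResult", consensus = consensus, area = area,
      deltaArea = deltaA, chosenK = as.numeric(chosen),
      assignments = assign, degenerate = FALSE)
}
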
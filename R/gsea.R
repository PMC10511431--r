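# Enrichment score from hit positions only: the running sum is piecewise
# linear between hits, so its extrema occur immediately after a hit or
# immediately before the next hit. O(|S|) instead of O(N).
esFromHits <- function(hitIdx, hitWeights, N) {
  m <- length(hitIdx)
  ord <- order(hitIdx)
  idx <- hitIdx[ord]
  w <- hitWeights[ord]
  sumw <- sum(w)
  if (sumw == 0) w <- rep(1 / m, m) else w <- w / sumw
  miss <- 1 / (N - m)
  cumW <- cumsum(w)
  afterHit <- cumW - (idx - seq_len(m)) * miss
  beforeHit <- c(0, cumW[-m]) - (idx - seq_len(m)) * miss
  # interleave in list-position order so magnitude ties break exactly as in
  # the full running sum (earliest position wins)
  cand <- as.vector(rbind(beforeHit, afterHit))
  cand[which.max(round(abs(cand), 10))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Computes the classic pre-ranked geneset enrichment score: walking down the
#' ranked list, membership hits increment the running sum by
#' `|score|^exponent` (normalised by the sum over hits) and misses decrement
#' it by `1/(N - |S|)`; the ES is the signed maximum-magnitude deviation.
#'
#' @param ranked Named numeric vector of scores (e.g. Spearman rho with the
#'   query gene), sorted in decreasing order; names are gene ids.
#' @param geneset Character vector of gene ids.
#' @param exponent Weight power on the scores (0 = unweighted KS statistic,
#'   1 = classic weighted default).
#' @return List with `es` and `running` (the full running sum, one value per
#'   ranked gene).
#' @export
enrichmentScore <- function(ranked, geneset, exponent = 1) {
  if (is.unsorted(rev(ranked))) ranked <- sort(ranked, decreasing = TRUE)
  N <- length(ranked)
  hit <- names(ranked) %in% geneset
  m <- sum(hit)
  if (m == 0L) stop("geneset is disjoint from the ranked list")
  if (m == N) stop("geneset equals the entire ranked list (degenerate)")
  w <- abs(ranked)^exponent
  w[!hit] <- 0
  sumw <- sum(w)
  if (sumw == 0) w[hit] <- 1 / m else w <- w / sumw
  step <- ifelse(hit, w, -1 / (N - m))
  running <- cumsum(step)
  # round before the argmax so exact-magnitude ties (positive vs negative
  # excursion differing only in float error) break by position
  es <- running[which.max(round(abs(running), 10))]
  list(es = es, running = running)
}

#' Permutation-normalised enrichment over a geneset collection
#'
#' For every geneset, the null distribution of the ES is built by
#' size-preserving gene-label permutation (random draws of `|S|` genes from
#' the ranked universe), and:
#' \itemize{
#'   \item NES = ES / mean(|permutation ES| of the same sign);
#'   \item nominal p = same-sign tail proportion with add-one smoothing;
#'   \item FDR q = the standard NES-based ratio-of-tails estimate, computed
#'     separately for positive and negative NES and capped at 1.
#' }
#'
#' @param ranked Named numeric scores sorted decreasing (sorted internally if
#'   not).
#' @param collection A [GeneSetCollection-class].
#' @param nPerm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @param exponent Score weight power (default 1).
#' @param context Context label stored on the result.
#' @return data.frame with columns `geneset`, `size`, `ES`, `NES`, `p`, `q`,
#'   `n_perm`, `seed`; attribute `context`.
#' @export
normalizedEnrichment <- function(ranked, collection, nPerm = 1000, seed = 7,
                                 exponent = 1, context = "ALL") {
  stopifnot(nPerm >= 100)
  ranked <- sort(ranked, decreasing = TRUE)
  N <- length(ranked)
  absW <- abs(ranked)^exponent
  sets <- geneSets(collection)
  sizes <- vapply(sets, function(s) sum(names(ranked) %in% s), integer(1))

  obsES <- vapply(names(sets), function(nm)
    enrichmentScore(ranked, sets[[nm]], exponent)$es, numeric(1))

  # one permutation null per distinct effective set size
  set.seed(seed)
  uniqSizes <- sort(unique(sizes[sizes > 0 & sizes < N]))
  permES <- list()
  for (m in uniqSizes) {
    es <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
      idx <- sample.int(N, m)
      es[b] <- esFromHits(idx, absW[idx], N)
    }
    permES[[as.character(m)]] <- es
  }

  nes <- p <- rep(NA_real_, length(sets))
  permNESpool <- numeric()
  for (i in seq_along(sets)) {
    m <- sizes[i]
    if (m == 0L || m == N) next
    null <- permES[[as.character(m)]]
    es <- obsES[i]
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    if (!length(same)) {
      warning("geneset '", names(sets)[i],
              "' has no same-sign permutation ES; NES recorded missing")
      next
    }
    nes[i] <- es / mean(abs(same))
    p[i] <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  }

  # pooled permutation NES for the ratio-of-tails FDR
  for (m in uniqSizes) {
    null <- permES[[as.character(m)]]
    posMean <- mean(null[null >= 0])
    negMean <- mean(abs(null[null < 0]))
    pn <- ifelse(null >= 0,
                 if (is.nan(posMean)) NA_real_ else null / posMean,
                 if (is.nan(negMean)) NA_real_ else null / negMean)
    permNESpool <- c(permNESpool, pn[!is.na(pn)])
  }

  q <- rep(NA_real_, length(sets))
  obsNES <- nes[!is.na(nes)]
  for (i in seq_along(sets)) {
    if (is.na(nes[i])) next
    if (nes[i] >= 0) {
      denomPerm <- sum(permNESpool >= 0)
      tailPerm <- if (denomPerm) sum(permNESpool >= nes[i]) / denomPerm else NA
      denomObs <- sum(obsNES >= 0)
      tailObs <- if (denomObs) sum(obsNES >= nes[i]) / denomObs else NA
    } else {
      denomPerm <- sum(permNESpool < 0)
      tailPerm <- if (denomPerm) sum(permNESpool <= nes[i]) / denomPerm else NA
      denomObs <- sum(obsNES < 0)
      tailObs <- if (denomObs) sum(obsNES <= nes[i]) / denomObs else NA
    }
    if (!is.na(tailPerm) && !is.na(tailObs) && tailObs > 0)
      q[i] <- min(1, tailPerm / tailObs)
  }

  out <- data.frame(geneset = names(sets), size = sizes, ES = unname(obsES),
                    NES = nes, p = p, q = q, n_perm = nPerm, seed = seed,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "context") <- context
  out
}

#' Genesets significant in at least one context
#'
#' A geneset is reported pan-cancer iff it passes `q < fdrMax` and
#' `|NES| > nesMinAbs` in at least one context; per-context values are then
#' retained for every reported set (heatmap semantics).
#'
#' @param results data.frame combining [normalizedEnrichment()] outputs with a
#'   `context` column (use [bindContexts()]).
#' @param fdrMax FDR cutoff (default 0.001, i.e. 0.1%).
#' @param nesMinAbs Absolute NES cutoff (default 2.3).
#' @return Subset of `results` restricted to reported sets, with a logical
#'   `passes` column marking the qualifying rows.
#' @export
significantGenesets <- function(results, fdrMax = 0.001, nesMinAbs = 2.3) {
  stopifnot(all(c("geneset", "NES", "q") %in% names(results)))
  if (!"context" %in% names(results)) results$context <- "ALL"
  pass <- !is.na(results$q) & !is.na(results$NES) &
    results$q < fdrMax & abs(results$NES) > nesMinAbs
  keep <- unique(results$geneset[pass])
  out <- results[results$geneset %in% keep, , drop = FALSE]
  out$passes <- pass[results$geneset %in% keep]
  rownames(out) <- NULL
  out
}

#' Stack per-context result tables into one data.frame
#'
#' @param results Named list of per-context data.frames (names become the
#'   `context` column; unnamed lists fall back to each table's `context`
#'   attribute).
#' @return One data.frame with a `context` column.
#' @export
bindContexts <- function(results) {
  nm <- names(results)
  out <- lapply(seq_along(results), function(i) {
    df <- results[[i]]
    ctx <- if (!is.null(nm) && nzchar(nm[i])) nm[i]
           else attr(df, "context") %||% as.character(i)
    df$context <- ctx
    df
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge geneset collections into one testing collection
#'
#' Merges several collections (e.g. a hallmark collection, a pathway
#' collection, custom senescence/P53 sets and a knock-out signature) while
#' preserving provenance labels. Name collisions are an error.
#'
#' @param ... [GeneSetCollection-class] objects.
#' @return A merged [GeneSetCollection-class].
#' @export
assembleCollection <- function(...) {
  colls <- list(...)
  stopifnot(all(vapply(colls, is, logical(1), "GeneSetCollection")))
  allNames <- unlist(lapply(colls, names))
  dup <- unique(allNames[duplicated(allNames)])
  if (length(dup)) stop("geneset name collision: ",
                        paste(dup, collapse = ", "))
  sets <- do.call(c, lapply(colls, geneSets))
  prov <- unlist(lapply(colls, function(x) x@provenance))
  GeneSetCollection(sets, provenance = prov)
}
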
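# shared fixture builders -----------------------------------------------

# tiny study: a couple of cancer types, small gene universe
tinySpec <- function(nSamples = 120, nTypes = 2, nGenes = 200, seed = 42,
                     ...) {
  syntheticSpec(
    cancerTypes = data.frame(acronym = sprintf("TT%02d", seq_len(nTypes)),
                             n_samples = nSamples),
    nGenes = nGenes, seed = seed, ...)
}

# independent brute-force Spearman: rank with mid-ranks, then the Pearson
# product-moment formula written out by hand
bruteSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# textbook Benjamini-Hochberg step-up, written independently of p.adjust
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# brute-force enrichment score by full running-sum enumeration
bruteES <- function(scores, geneset, exponent = 1) {
  scores <- sort(scores, decreasing = TRUE)
  hit <- names(scores) %in% geneset
  N <- length(scores); m <- sum(hit)
  w <- abs(scores)^exponent
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1 / m else w <- w / sum(w)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) w[i] else -1 / (N - m)
    run[i] <- cur
  }
  run[which.max(round(abs(run), 10))]
}

# a small GMT file on disk
writeTempGmt <- function(lines) {
  f <- tempfile(fileext = ".gmt")
  writeLines(lines, f)
  f
}
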
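# Deterministic substream seed: polynomial hash of a stream tag folded into
# the master seed, kept below 2^31 so set.seed() accepts it.
seedFor <- function(seed, tag) {
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 131 + code) %% 1977326743
  as.integer((abs(seed) %% 1e6 * 2147 + h) %% 2147483647)
}

# softplus-style monotone marginal onto the log10(x+1) expression scale;
# strictly increasing in z, always >= 0
latentToExpr <- function(z, mu = 1.2) log10(1 + exp(mu + z))

# exact normal-copula relation between the latent Pearson r and the target
# Spearman rho
copulaR <- function(rho) 2 * sin(pi * rho / 6)

#' Define a synthetic multi-cancer study
#'
#' Builds a validated [SyntheticSpec-class]. The defaults describe the study
#' conditions used throughout the package's own evaluations: ten cancer types
#' of 300 samples, a 40% mutation fraction, one positively (rho = 0.7) and one
#' negatively (rho = -0.7) co-expressed 50-gene module, one stratum-switching
#' module (rho = -0.4 in wild-type, +0.4 in mutant samples), per-type log
#' hazard ratios spanning -1.2..1.2 for high-vs-low query expression with 30%
#' uniform censoring, a three-compound drug panel (sensitising, resistance,
#' null), and an mRNA-protein correlation target of 0.62.
#'
#' @param cancerTypes data.frame with `acronym` and `n_samples`, optionally
#'   `mut_fraction`, `log_hr`, `baseline_rate`, `censor_rate`, `query_shift`,
#'   `n_lines`; missing columns are filled with defaults.
#' @param nGenes Total genes, query gene included.
#' @param queryGene Symbol of the query gene.
#' @param modules List of module descriptors (`name`, `size`, `rho`); `rho`
#'   is a scalar, a per-acronym named vector, or `list(WT=, MUT=)`.
#' @param drugPanel data.frame with `compound` and `slope` (latent logit slope
#'   linking query expression to AUC; negative slope = high expression is
#'   sensitising).
#' @param proteinCor Target Pearson correlation of query mRNA with the summed
#'   protein channels.
#' @param seed Integer master seed.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(cancerTypes = NULL, nGenes = 2000,
                          queryGene = "QGENE", modules = NULL,
                          drugPanel = NULL, proteinCor = 0.62, seed = 1) {
  if (is.null(cancerTypes)) {
    nT <- 10L
    cancerTypes <- data.frame(
      acronym = sprintf("CT%02d", seq_len(nT)),
      n_samples = 300L)
  }
  nT <- nrow(cancerTypes)
  if (is.null(cancerTypes$mut_fraction)) cancerTypes$mut_fraction <- 0.4
  if (is.null(cancerTypes$log_hr))
    cancerTypes$log_hr <- round(seq(-1.2, 1.2, length.out = nT), 2)
  if (is.null(cancerTypes$baseline_rate)) cancerTypes$baseline_rate <- 0.002
  if (is.null(cancerTypes$censor_rate)) cancerTypes$censor_rate <- 0.3
  if (is.null(cancerTypes$query_shift)) cancerTypes$query_shift <- 0
  if (is.null(cancerTypes$n_lines)) cancerTypes$n_lines <- 30L
  if (is.null(modules)) {
    # default module size 50, shrunk to fit small gene universes
    msz <- min(50L, max(1L, floor((nGenes - 1) / 3)))
    modules <- list(
      list(name = "POS", size = msz, rho = 0.7),
      list(name = "NEG", size = msz, rho = -0.7),
      list(name = "STRAT", size = msz, rho = list(WT = -0.4, MUT = 0.4)))
  }
  if (is.null(drugPanel)) drugPanel <- data.frame(
    compound = c("drug_sens", "drug_resist", "drug_null"),
    slope = c(-2, 2, 0), stringsAsFactors = FALSE)
  new("SyntheticSpec", cancerTypes = cancerTypes, nGenes = nGenes,
      queryGene = queryGene, modules = modules, drugPanel = drugPanel,
      proteinCor = proteinCor, seed = seed)
}

# gene universe: query first, then module genes, then null filler
# (AURKA is planted among the null genes as the proliferation covariate)
syntheticGeneIds <- function(spec) {
  mods <- spec@modules
  moduleGenes <- unlist(lapply(mods, function(m)
    sprintf("%s_%03d", m$name, seq_len(m$size))), use.names = FALSE)
  nNull <- spec@nGenes - 1L - length(moduleGenes)
  nullGenes <- if (nNull > 0) sprintf("NULL_%05d", seq_len(nNull))
               else character()
  if (nNull > 0) nullGenes[length(nullGenes)] <- "AURKA"
  c(spec@queryGene, moduleGenes, nullGenes)
}

moduleRho <- function(m, acronym, stratum) {
  r <- m$rho
  if (is.list(r)) {
    r <- r[[stratum]]
    if (is.null(r)) stop("module '", m$name, "': no rho for stratum ", stratum)
  }
  val <- if (!is.null(names(r))) {
    if (!acronym %in% names(r)) stop("module '", m$name,
                                     "': no rho for type ", acronym)
    unname(r[[acronym]])
  } else r[[1L]]
  if (abs(val) >= 1) stop("module '", m$name, "': infeasible rho ", val)
  val
}

# expected censored fraction for T ~ Exp(rate), C ~ U(0, tmax):
# P(C < T) = (1 - exp(-a*tmax)) / (a*tmax)
censFrac <- function(tmax, rates) {
  mean(vapply(rates, function(a)
    (1 - exp(-a * tmax)) / (a * tmax), numeric(1)))
}

#' Generate a synthetic multi-cancer cohort
#'
#' Within each cancer type, a latent standard-normal query variable drives
#' module genes through a Gaussian copula whose latent Pearson parameter is
#' `2 sin(pi * rho / 6)`, so each module gene attains its target Spearman
#' correlation with the query gene after the strictly monotone marginal map
#' onto the log10(x+1) scale. Mutation status is Bernoulli per sample; for
#' stratum-specific modules the copula parameter switches with status.
#' Survival times are exponential with log hazard `log_hr * [query > within-
#' type median]`; censoring is independent uniform on `[0, Tmax]` with `Tmax`
#' solved so the expected censored fraction matches `censor_rate`. Ordinal
#' tumor size / node / metastasis covariates and the AURKA expression
#' covariate are attached for multivariate survival models. Fully reproducible
#' from the spec seed via per-type, per-component substreams, so enlarging the
#' gene universe never perturbs the survival draws.
#'
#' @param spec A [SyntheticSpec-class].
#' @return List with `expr` (gene-by-sample matrix), `annotations`
#'   (data.frame) and `cohort` (the two bundled as a `SummarizedExperiment`).
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  genes <- syntheticGeneIds(spec)
  ct <- spec@cancerTypes
  exprBlocks <- vector("list", nrow(ct))
  annBlocks <- vector("list", nrow(ct))
  geneMu <- 1.0 + 0.4 * ((seq_along(genes) * 37L) %% 11L) / 10
  names(geneMu) <- genes
  for (k in seq_len(nrow(ct))) {
    acr <- ct$acronym[k]; n <- ct$n_samples[k]
    sampleIds <- sprintf("%s_S%04d", acr, seq_len(n))

    set.seed(seedFor(spec@seed, paste0("status:", acr)))
    mut <- rbinom(n, 1L, ct$mut_fraction[k]) == 1L
    cls <- ifelse(mut,
                  ifelse(rbinom(n, 1L, 0.5) == 1L,
                         "TruncatingHomDel", "InframeMissense"),
                  "WT")

    set.seed(seedFor(spec@seed, paste0("expr:", acr)))
    z0 <- rnorm(n)
    mat <- matrix(NA_real_, nrow = length(genes), ncol = n,
                  dimnames = list(genes, sampleIds))
    mat[spec@queryGene, ] <- latentToExpr(
      z0, geneMu[spec@queryGene] + ct$query_shift[k])
    idx <- 2L
    for (m in spec@modules) {
      stratumSpecific <- is.list(m$rho)
      rWT <- copulaR(moduleRho(m, acr, "WT"))
      rMUT <- if (stratumSpecific) copulaR(moduleRho(m, acr, "MUT")) else rWT
      r <- ifelse(mut, rMUT, rWT)
      for (j in seq_len(m$size)) {
        z <- r * z0 + sqrt(1 - r^2) * rnorm(n)
        mat[idx, ] <- latentToExpr(z, geneMu[idx])
        idx <- idx + 1L
      }
    }
    if (idx <= length(genes)) {
      nNull <- length(genes) - idx + 1L
      zn <- matrix(rnorm(nNull * n), nrow = nNull)
      mat[idx:length(genes), ] <- latentToExpr(zn, geneMu[idx:length(genes)])
    }

    set.seed(seedFor(spec@seed, paste0("surv:", acr)))
    q <- mat[spec@queryGene, ]
    high <- q > median(q)
    rate <- ct$baseline_rate[k] * exp(ct$log_hr[k] * high)
    tEvent <- rexp(n, rate)
    cr <- ct$censor_rate[k]
    if (cr > 0) {
      scale0 <- 1 / mean(rate)
      tmax <- uniroot(function(tm) censFrac(tm, rate) - cr,
                      lower = scale0 * 1e-4, upper = scale0 * 1e6,
                      tol = scale0 * 1e-8)$root
      cTime <- runif(n, 0, tmax)
    } else cTime <- rep(Inf, n)
    osTime <- pmin(tEvent, cTime)
    osEvent <- tEvent <= cTime

    set.seed(seedFor(spec@seed, paste0("covar:", acr)))
    annBlocks[[k]] <- data.frame(
      sample_id = sampleIds, cancer_type = acr,
      tp53_status = ifelse(mut, "MUT", "WT"), tp53_class = cls,
      os_time = osTime, os_event = osEvent,
      size_stage = sample(1:4, n, replace = TRUE),
      node_stage = sample(0:3, n, replace = TRUE),
      met_stage = sample(0:1, n, replace = TRUE),
      AURKA = unname(mat["AURKA", ]),
      stringsAsFactors = FALSE)
    exprBlocks[[k]] <- mat
  }
  expr <- do.call(cbind, exprBlocks)
  ann <- do.call(rbind, annBlocks)
  list(expr = expr, annotations = ann, cohort = queryCohort(expr, ann))
}

#' Generate a synthetic cell-line panel
#'
#' Query expression per line is drawn as in [generateCohort()]; each
#' compound's AUC is `plogis(intercept + slope * standardized query expression
#' + noise)`, so AUC lies in (0,1) and the slope sign controls the planted
#' expression-response correlation. The protein channel is planted on the
#' observed expression scale: the summed isoform signal has Pearson
#' correlation `proteinCor` with query mRNA in expectation. A configurable
#' number of engineered and fibroblast decoy lines (with expression but no
#' cancer-type structure) is appended.
#'
#' @param spec A [SyntheticSpec-class].
#' @param nDecoys Engineered and fibroblast lines each.
#' @param aucNoise SD of the latent logit noise.
#' @param missingAuc Fraction of (line, compound) pairs left untested.
#' @return A [CellLinePanel-class].
#' @export
generateCellLinePanel <- function(spec, nDecoys = 2L, aucNoise = 0.6,
                                  missingAuc = 0) {
  validObject(spec)
  ct <- spec@cancerTypes
  genes <- syntheticGeneIds(spec)
  geneMu <- 1.0 + 0.4 * ((seq_along(genes) * 37L) %% 11L) / 10
  names(geneMu) <- genes
  blocks <- list(); metas <- list()
  for (k in seq_len(nrow(ct))) {
    acr <- ct$acronym[k]; n <- ct$n_lines[k]
    set.seed(seedFor(spec@seed, paste0("lines:", acr)))
    ids <- sprintf("%s_L%03d", acr, seq_len(n))
    z0 <- rnorm(n)
    mat <- matrix(NA_real_, length(genes), n, dimnames = list(genes, ids))
    mat[spec@queryGene, ] <- latentToExpr(z0, geneMu[spec@queryGene])
    idx <- 2L
    for (m in spec@modules) {
      r <- copulaR(moduleRho(m, acr, "WT"))
      for (j in seq_len(m$size)) {
        mat[idx, ] <- latentToExpr(r * z0 + sqrt(1 - r^2) * rnorm(n),
                                   geneMu[idx])
        idx <- idx + 1L
      }
    }
    if (idx <= length(genes)) {
      nNull <- length(genes) - idx + 1L
      mat[idx:length(genes), ] <- latentToExpr(
        matrix(rnorm(nNull * n), nNull), geneMu[idx:length(genes)])
    }
    blocks[[k]] <- mat
    metas[[k]] <- data.frame(cell_line = ids, cancer_type = acr,
                             lineage = "Tumor", stringsAsFactors = FALSE)
  }
  expr <- do.call(cbind, blocks)
  meta <- do.call(rbind, metas)

  if (nDecoys > 0) {
    set.seed(seedFor(spec@seed, "decoys"))
    dId <- c(sprintf("ENG_L%03d", seq_len(nDecoys)),
             sprintf("FIB_L%03d", seq_len(nDecoys)))
    dExpr <- latentToExpr(matrix(rnorm(length(genes) * 2 * nDecoys),
                                 length(genes)), geneMu)
    dimnames(dExpr) <- list(genes, dId)
    expr <- cbind(expr, dExpr)
    meta <- rbind(meta, data.frame(
      cell_line = dId, cancer_type = "ENGINEERED",
      lineage = rep(c("Engineered", "Fibroblast"), each = nDecoys),
      stringsAsFactors = FALSE))
  }

  q <- expr[spec@queryGene, ]
  zq <- as.numeric(scale(q))
  set.seed(seedFor(spec@seed, "auc"))
  aucRows <- list()
  for (i in seq_len(nrow(spec@drugPanel))) {
    comp <- spec@drugPanel$compound[i]
    slope <- spec@drugPanel$slope[i]
    val <- plogis(slope * zq + rnorm(length(zq), 0, aucNoise))
    if (missingAuc > 0)
      val[runif(length(val)) < missingAuc] <- NA_real_
    aucRows[[i]] <- data.frame(cell_line = colnames(expr), compound = comp,
                               auc = val, source = "synthetic",
                               stringsAsFactors = FALSE)
  }
  auc <- do.call(rbind, aucRows)
  auc <- auc[!is.na(auc$auc), , drop = FALSE]  # untested pairs simply absent
  rownames(auc) <- NULL

  set.seed(seedFor(spec@seed, "protein"))
  r <- spec@proteinCor
  total <- r * zq + sqrt(1 - r^2) * rnorm(length(zq))
  protein <- rbind(total / 3 + rnorm(length(zq), 0, 0.01),
                   total / 3 + rnorm(length(zq), 0, 0.01),
                   total / 3 + rnorm(length(zq), 0, 0.01))
  rownames(protein) <- sprintf("%s_iso%d", spec@queryGene, 1:3)
  colnames(protein) <- colnames(expr)

  CellLinePanel(expr, meta, auc, protein)
}

#' Generate planted and null genesets for a synthetic study
#'
#' Emits genesets drawn from the positively and/or negatively correlated
#' planted modules, plus size-matched random null sets drawn from the
#' unplanted genes.
#'
#' @param spec A [SyntheticSpec-class].
#' @param which Subset of `c("positive", "negative", "null")`; empty gives an
#'   empty collection.
#' @param setSize Genes per set.
#' @param nNull Number of null sets.
#' @return A [GeneSetCollection-class] with provenance labels
#'   `planted-positive`, `planted-negative`, `null`.
#' @export
generateGenesets <- function(spec, which = c("positive", "negative", "null"),
                             setSize = 50L, nNull = 3L) {
  validObject(spec)
  if (!length(which)) return(GeneSetCollection())
  which <- match.arg(which, several.ok = TRUE)
  genes <- syntheticGeneIds(spec)
  sets <- list(); prov <- character()
  pickModule <- function(sign) {
    for (m in spec@modules) {
      r <- if (is.list(m$rho)) NULL else mean(unlist(m$rho))
      if (!is.null(r) && sign * r > 0) return(m)
    }
    NULL
  }
  moduleGenes <- function(m) grep(paste0("^", m$name, "_"), genes,
                                  value = TRUE)
  set.seed(seedFor(spec@seed, "genesets"))
  if ("positive" %in% which) {
    m <- pickModule(+1)
    if (!is.null(m)) {
      g <- moduleGenes(m)
      if (setSize > length(g)) stop("requested set size ", setSize,
                                    " exceeds module size ", length(g))
      sets[["PLANTED_POS"]] <- sample(g, setSize)
      prov <- c(prov, "planted-positive")
    }
  }
  if ("negative" %in% which) {
    m <- pickModule(-1)
    if (!is.null(m)) {
      g <- moduleGenes(m)
      if (setSize > length(g)) stop("requested set size ", setSize,
                                    " exceeds module size ", length(g))
      sets[["PLANTED_NEG"]] <- sample(g, setSize)
      prov <- c(prov, "planted-negative")
    }
  }
  if ("null" %in% which && nNull > 0) {
    pool <- grep("^NULL_", genes, value = TRUE)
    if (setSize > length(pool)) stop("requested set size ", setSize,
                                     " exceeds null pool ", length(pool))
    for (i in seq_len(nNull)) {
      sets[[sprintf("NULL_SET_%02d", i)]] <- sample(pool, setSize)
      prov <- c(prov, "null")
    }
  }
  GeneSetCollection(sets, provenance = if (length(prov)) prov else character())
}
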
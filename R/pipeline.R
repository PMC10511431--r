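#' Declarative configuration for a full pipeline run
#'
#' Collects all inputs, thresholds and seeds for [runPipeline()]. Inputs are
#' either file paths (`exprPath`, `clinicalPath`, plus optional `gmtPaths`)
#' in the dialects of [readExpressionMatrix()] / [readSampleAnnotation()] /
#' [readGmt()], or an in-memory synthetic study via `syntheticSpec` (files
#' win when both are given). All thresholds default to the pipeline's
#' standard values: correlation screen 0.6; GSEA FDR 0.001 with |NES| > 2.3;
#' stratification gate > 20 per stratum; delta thresholds 0.6 (significance)
#' and 2.3 (reporting); survival gates 10 events and 3-of-4 covariates in 20
#' patients; pharmaco gates 10 lines / 2 per response class at AUC 0.8.
#'
#' @param queryGene Query gene symbol.
#' @param outDir Output directory (created if needed).
#' @param exprPath,clinicalPath,gmtPaths Optional input files.
#' @param syntheticSpec Optional [SyntheticSpec-class] used when no files are
#'   given.
#' @param corThreshold,gseaFdr,gseaNesMin,deltaCorThreshold,deltaNesSig,
#'   deltaNesReport,stratMinPerGroup,minEvents,minCovPatients,
#'   pharmacoMinLines,pharmacoMinClass,aucCut Thresholds (see description).
#' @param nPerm GSEA permutations.
#' @param clusterReps Consensus-clustering repetitions.
#' @param seed Master seed for every random stage.
#' @param stages Named logical vector toggling stages.
#' @return A validated `pipelineConfig` list.
#' @export
pipelineConfig <- function(queryGene, outDir,
                           exprPath = NULL, clinicalPath = NULL,
                           gmtPaths = NULL, syntheticSpec = NULL,
                           corThreshold = 0.6, gseaFdr = 0.001,
                           gseaNesMin = 2.3, deltaCorThreshold = 0.6,
                           deltaNesSig = 0.6, deltaNesReport = 2.3,
                           stratMinPerGroup = 20, minEvents = 10,
                           minCovPatients = 20, pharmacoMinLines = 10,
                           pharmacoMinClass = 2, aucCut = 0.8,
                           nPerm = 1000, clusterReps = 1000, seed = 7,
                           stages = c(coexpr = TRUE, gsea = TRUE,
                                      stratify = TRUE, survive = TRUE,
                                      meta = TRUE, cluster = TRUE,
                                      pharmaco = TRUE)) {
  thr <- c(corThreshold, gseaFdr, gseaNesMin, deltaCorThreshold, deltaNesSig,
           deltaNesReport, stratMinPerGroup, minEvents, minCovPatients,
           pharmacoMinLines, pharmacoMinClass, aucCut)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  if (is.null(exprPath) != is.null(clinicalPath))
    stop("exprPath and clinicalPath must be given together")
  if (is.null(exprPath) && is.null(syntheticSpec))
    stop("either input files or a syntheticSpec is required")
  if (!is.null(exprPath)) {
    for (pth in c(exprPath, clinicalPath, gmtPaths))
      if (!file.exists(pth)) stop("input not found: ", pth)
  }
  structure(list(
    queryGene = queryGene, outDir = outDir, exprPath = exprPath,
    clinicalPath = clinicalPath, gmtPaths = gmtPaths,
    syntheticSpec = syntheticSpec, corThreshold = corThreshold,
    gseaFdr = gseaFdr, gseaNesMin = gseaNesMin,
    deltaCorThreshold = deltaCorThreshold, deltaNesSig = deltaNesSig,
    deltaNesReport = deltaNesReport, stratMinPerGroup = stratMinPerGroup,
    minEvents = minEvents, minCovPatients = minCovPatients,
    pharmacoMinLines = pharmacoMinLines,
    pharmacoMinClass = pharmacoMinClass, aucCut = aucCut, nPerm = nPerm,
    clusterReps = clusterReps, seed = seed, stages = stages),
    class = "pipelineConfig")
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", eol = "\n")
  path
}

#' Run the full pan-cancer association pipeline
#'
#' Executes the stages in dependency order — gene filter and per-cancer
#' co-expression profiles, GSEA on the correlation-ranked lists, TP53
#' stratification (expression comparisons, delta correlation, delta NES),
#' survival screen, second-order correlation-vs-hazard analyses, consensus
#' clustering of cancer types, and the cell-line drug screen — writing one
#' TSV per output into `config$outDir` plus a manifest with MD5 content
#' hashes and a run log recording the package version, seed and thresholds.
#' A stage failure halts its dependents but independent stages continue; the
#' per-stage status is returned and logged.
#'
#' @param config A [pipelineConfig()].
#' @return Invisibly, a list with `manifest` (data.frame of files + hashes),
#'   `status` (per-stage character), and the in-memory stage `results`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$outDir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  logMsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    writeLines(line, logCon)
    message(line)
  }
  logMsg("pancontext ", as.character(utils::packageVersion("pancontext")),
         " | query=", config$queryGene, " | seed=", config$seed)
  logMsg("thresholds: cor=", config$corThreshold, " gseaFdr=",
         config$gseaFdr, " nes=", config$gseaNesMin, " delta=",
         config$deltaCorThreshold, "/", config$deltaNesSig, "/",
         config$deltaNesReport, " surv=", config$minEvents, "ev/",
         config$minCovPatients, "pt pharmaco=", config$pharmacoMinLines,
         "/", config$pharmacoMinClass, "@", config$aucCut)

  status <- c()
  results <- list()
  files <- character()
  enabled <- function(st) isTRUE(config$stages[[st]])

  # ---- inputs -------------------------------------------------------------
  panel <- NULL
  genesets <- NULL
  if (!is.null(config$exprPath)) {
    expr <- readExpressionMatrix(config$exprPath)
    ann <- readSampleAnnotation(config$clinicalPath)
    ann <- ann[ann$sample_id %in% colnames(expr), , drop = FALSE]
    expr <- expr[, ann$sample_id, drop = FALSE]
    if (!is.null(config$gmtPaths)) {
      colls <- lapply(config$gmtPaths, readGmt)
      genesets <- do.call(assembleCollection, colls)
    }
  } else {
    sim <- generateCohort(config$syntheticSpec)
    expr <- sim$expr
    ann <- sim$annotations
    genesets <- generateGenesets(config$syntheticSpec)
    panel <- generateCellLinePanel(config$syntheticSpec)
  }
  logMsg("inputs: ", nrow(expr), " genes x ", ncol(expr), " samples, ",
         length(unique(ann$cancer_type)), " cancer types")

  runStage <- function(name, deps, fun) {
    if (!enabled(name)) { status[name] <<- "disabled"; return(invisible()) }
    failedDeps <- deps[vapply(deps, function(d)
      !identical(status[[d]], "ok"), logical(1))]
    if (length(failedDeps)) {
      status[name] <<- paste0("skipped (needs ",
                              paste(failedDeps, collapse = ","), ")")
      logMsg("stage ", name, ": ", status[name])
      return(invisible())
    }
    res <- tryCatch({
      out <- fun()
      status[name] <<- "ok"
      out
    }, error = function(e) {
      status[name] <<- paste0("failed: ", conditionMessage(e))
      logMsg("stage ", name, " FAILED: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      results[[name]] <<- res
      logMsg("stage ", name, ": ok")
    }
    invisible()
  }

  # ---- coexpr -------------------------------------------------------------
  runStage("coexpr", character(), function() {
    groups <- setNames(ann$cancer_type, ann$sample_id)
    kept <- filterGenes(expr, groups, queryGene = config$queryGene)
    exprF <- expr[kept, , drop = FALSE]
    profiles <- list()
    countRows <- list()
    for (ct in unique(ann$cancer_type)) {
      ids <- ann$sample_id[ann$cancer_type == ct]
      pr <- spearmanProfile(exprF, config$queryGene, ids,
                            context = paste0(ct, ":ALL"))
      profiles[[ct]] <- pr
      sg <- significantGenes(pr, config$corThreshold)
      countRows[[ct]] <- data.frame(
        cancer_type = ct, n_samples = length(ids),
        mean_query = mean(exprF[config$queryGene, ids], na.rm = TRUE),
        positive = sg$counts[["positive"]],
        negative = sg$counts[["negative"]],
        total = sg$counts[["total"]], stringsAsFactors = FALSE)
      files <<- c(files, writeTsv(pr, file.path(
        config$outDir, paste0("coexpr_", ct, ".tsv"))))
    }
    counts <- do.call(rbind, countRows)
    union <- unionCorrelatedGenes(profiles, config$corThreshold)
    files <<- c(files, writeTsv(counts,
                                file.path(config$outDir,
                                          "coexpr_counts.tsv")))
    files <<- c(files, writeTsv(
      data.frame(gene = rownames(union$rhoMatrix), union$rhoMatrix,
                 check.names = FALSE),
      file.path(config$outDir, "coexpr_union_rho.tsv")))
    lvl <- countsVsLevel(counts, setNames(counts$mean_query,
                                          counts$cancer_type))
    files <<- c(files, writeTsv(
      data.frame(measure = names(lvl), rho = unname(lvl)),
      file.path(config$outDir, "coexpr_counts_vs_level.tsv")))
    list(expr = exprF, profiles = profiles, counts = counts, union = union,
         countsVsLevel = lvl)
  })

  # ---- gsea ---------------------------------------------------------------
  runStage("gsea", "coexpr", function() {
    if (is.null(genesets) || length(genesets) == 0)
      stop("no geneset collection available")
    perCtx <- list()
    for (ct in names(results$coexpr$profiles)) {
      pr <- results$coexpr$profiles[[ct]]
      ranked <- setNames(pr$rho, pr$gene)
      ranked <- ranked[!is.na(ranked)]
      perCtx[[ct]] <- normalizedEnrichment(
        ranked, genesets, nPerm = config$nPerm, seed = config$seed,
        context = paste0(ct, ":ALL"))
    }
    all <- bindContexts(perCtx)
    sig <- significantGenesets(all, config$gseaFdr, config$gseaNesMin)
    files <<- c(files, writeTsv(all, file.path(config$outDir, "gsea.tsv")))
    files <<- c(files, writeTsv(sig, file.path(config$outDir,
                                               "gsea_significant.tsv")))
    list(perContext = perCtx, all = all, significant = sig)
  })

  # ---- stratify -----------------------------------------------------------
  runStage("stratify", "coexpr", function() {
    exprF <- results$coexpr$expr
    qv <- setNames(exprF[config$queryGene, ], colnames(exprF))
    ttests <- compareExpressionByStatus(qv, ann, "status")
    strat <- stratifiedProfiles(exprF, ann, config$queryGene,
                                config$stratMinPerGroup)
    deltas <- list()
    for (ct in names(strat)) {
      deltas[[ct]] <- deltaCorrelation(strat[[ct]]$WT, strat[[ct]]$MUT,
                                       config$deltaCorThreshold)
      files <<- c(files, writeTsv(deltas[[ct]], file.path(
        config$outDir, paste0("delta_cor_", ct, ".tsv"))))
    }
    unionDelta <- sort(unique(unlist(lapply(deltas, function(d)
      d$gene[d$significant]))))
    files <<- c(files, writeTsv(ttests, file.path(config$outDir,
                                                  "tp53_ttests.tsv")))
    files <<- c(files, writeTsv(
      data.frame(gene = unionDelta),
      file.path(config$outDir, "delta_cor_union.tsv")))
    deltaNesTables <- list()
    if (identical(status[["gsea"]], "ok") && length(strat)) {
      for (ct in names(strat)) {
        nesBoth <- lapply(c(WT = "WT", MUT = "MUT"), function(st) {
          pr <- strat[[ct]][[st]]
          ranked <- setNames(pr$rho, pr$gene)
          ranked <- ranked[!is.na(ranked)]
          normalizedEnrichment(ranked, genesets, nPerm = config$nPerm,
                               seed = config$seed,
                               context = paste0(ct, ":", st))
        })
        deltaNesTables[[ct]] <- deltaNes(nesBoth$WT, nesBoth$MUT,
                                         config$deltaNesSig,
                                         config$deltaNesReport)
        files <<- c(files, writeTsv(deltaNesTables[[ct]], file.path(
          config$outDir, paste0("delta_nes_", ct, ".tsv"))))
      }
    }
    list(ttests = ttests, profiles = strat, deltas = deltas,
         unionDelta = unionDelta, deltaNes = deltaNesTables)
  })

  # ---- survive ------------------------------------------------------------
  runStage("survive", character(), function() {
    grid <- survivalScreen(expr, ann, config$queryGene,
                           minEvents = config$minEvents,
                           minCovPatients = config$minCovPatients)
    files <<- c(files, writeTsv(grid, file.path(config$outDir,
                                                "survival_grid.tsv")))
    grid
  })

  # ---- meta ---------------------------------------------------------------
  runStage("meta", c("coexpr", "survive"), function() {
    grid <- results$survive
    uni <- grid[grid$stratum == "ALL" & grid$model == "univariate" &
                  !is.na(grid$HR), , drop = FALSE]
    hr <- setNames(uni$HR, uni$cancer_type)
    geneRes <- correlationVsHazard(results$coexpr$union$rhoMatrix, hr)
    files <<- c(files, writeTsv(geneRes$results, file.path(
      config$outDir, "correlation_vs_hazard.tsv")))
    nesRes <- NULL
    if (identical(status[["gsea"]], "ok")) {
      all <- results$gsea$all
      all$cancer_type <- sub(":ALL$", "", all$context)
      nesMat <- tapply(all$NES, list(all$geneset, all$cancer_type),
                       function(v) v[1L])
      nesRes <- nesVsHazard(nesMat, hr)
      files <<- c(files, writeTsv(nesRes$results, file.path(
        config$outDir, "nes_vs_hazard.tsv")))
    }
    list(gene = geneRes, geneset = nesRes, hr = hr)
  })

  # ---- cluster ------------------------------------------------------------
  runStage("cluster", "coexpr", function() {
    rhoM <- t(results$coexpr$union$rhoMatrix)
    kmax <- min(10L, nrow(rhoM) - 1L)
    if (kmax < 2L) stop("too few cancer types to cluster")
    cc <- consensusCluster(rhoM, kRange = 2:kmax,
                           reps = config$clusterReps, seed = config$seed)
    if (!cc@degenerate) {
      files <<- c(files, writeTsv(
        data.frame(cancer_type = names(clusterAssignments(cc)),
                   cluster = unname(clusterAssignments(cc))),
        file.path(config$outDir, "consensus_clusters.tsv")))
    }
    cc
  })

  # ---- pharmaco -----------------------------------------------------------
  runStage("pharmaco", character(), function() {
    if (is.null(panel)) stop("no cell-line panel available")
    fp <- suppressMessages(filterPanel(panel))
    screen <- drugScreen(fp, config$queryGene, config$aucCut,
                         config$pharmacoMinLines, config$pharmacoMinClass)
    nTypes <- length(unique(screen$cancer_type))
    rep <- reportableCompounds(screen,
                               minTypes = max(1L, ceiling(nTypes / 2)))
    mp <- mrnaProteinCorrelation(fp, config$queryGene)
    files <<- c(files, writeTsv(screen, file.path(config$outDir,
                                                  "drug_screen.tsv")))
    files <<- c(files, writeTsv(
      data.frame(cor = mp$cor, n = mp$n),
      file.path(config$outDir, "mrna_protein.tsv")))
    list(panel = fp, screen = screen, reportable = rep, mrnaProtein = mp)
  })

  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  writeTsv(manifest, file.path(config$outDir, "manifest.tsv"))
  for (st in names(status)) logMsg("status ", st, ": ", status[st])
  failed <- grepl("^failed", status)
  if (any(failed))
    warning("pipeline finished with failed stage(s): ",
            paste(names(status)[failed], collapse = ", "))
  invisible(list(manifest = manifest, status = status, results = results))
}
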
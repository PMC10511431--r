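#' Median dichotomization of a numeric vector
#'
#' Splits values at the sample median: `low` iff value <= median (ties go
#' low), `high` otherwise. Errors when no split is possible (all values
#' identical) or either group would be empty.
#'
#' @param values Numeric vector; `NA`s propagate.
#' @return Factor with levels `low`, `high` (low is the reference level, so a
#'   Cox coefficient on this factor is the log hazard of high vs low).
#' @export
dichotomizeByMedian <- function(values) {
  obs <- values[!is.na(values)]
  if (!length(obs)) stop("no observed values to dichotomize")
  med <- median(obs)
  lab <- ifelse(values <= med, "low", "high")
  if (all(obs <= med) || all(obs > med))
    stop("median split impossible: a group would be empty")
  factor(lab, levels = c("low", "high"))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimates per group and the log-rank chi-square statistic
#' (hypergeometric variance) with its p-value from a chi-square distribution
#' with 1 degree of freedom.
#'
#' @param times Follow-up times (days).
#' @param events Logical or 0/1 event indicator.
#' @param groups Two-level factor.
#' @return List with `fit` (a `survfit` object), `chisq`, `p`.
#' @export
kmLogrank <- function(times, events, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) == 0L)) stop("a group has zero samples")
  if (sum(events) < 1L) stop("at least one event required")
  s <- survival::Surv(times, as.numeric(events))
  sd <- survival::survdiff(s ~ groups)
  list(fit = survival::survfit(s ~ groups),
       chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Cox proportional-hazards fit for one context
#'
#' Fits a Cox model by partial-likelihood maximisation (Efron tie correction
#' by default, Breslow available) and reports the hazard ratio of the first
#' covariate column — by convention the high/low query-expression indicator —
#' with its Wald 95% CI and p-value. Non-convergence or monotone likelihood
#' (complete separation, detected by an unbounded coefficient or standard
#' error) yields a flagged result with missing HR rather than an error.
#'
#' @param covariates data.frame; the first column is the variable of interest
#'   (factor or numeric), remaining columns are adjustment covariates.
#' @param times,events Survival outcome.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return One-row data.frame: `N`, `n_events`, `HR`, `ci_lo`, `ci_hi`, `p`,
#'   `converged`, `covariates`.
#' @export
coxFit <- function(covariates, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(times))
  if (sum(events, na.rm = TRUE) < 1L) stop("at least one event required")
  dat <- cbind(data.frame(.time = times, .event = as.numeric(events)),
               covariates)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  flagged <- function() data.frame(
    N = nrow(dat), n_events = sum(dat$.event), HR = NA_real_,
    ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_, converged = FALSE,
    covariates = paste(names(covariates), collapse = "+"),
    stringsAsFactors = FALSE)
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(
        survival::Surv(.time, .event) ~ .,
        data = dat, ties = ties,
        control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
      warning = function(w) {
        if (grepl("infinite|converge|singular", conditionMessage(w)))
          invokeRestart("muffleWarning") else invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit)) return(flagged())
  sm <- summary(fit)
  co <- sm$coefficients
  se <- co[1L, "se(coef)"]
  beta <- co[1L, "coef"]
  if (!is.finite(beta) || !is.finite(se) || se > 1e3 || abs(beta) > 20)
    return(flagged())
  data.frame(
    N = nrow(dat), n_events = sum(dat$.event),
    HR = exp(beta),
    ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
    p = co[1L, "Pr(>|z|)"], converged = TRUE,
    covariates = paste(names(covariates), collapse = "+"),
    stringsAsFactors = FALSE)
}

#' Survival screen of the dichotomized query gene
#'
#' For every cancer type and stratum (ALL, and TP53 WT/MUT where eligible),
#' the query gene is dichotomized at the within-context median and a
#' univariate Cox model is fitted when at least `minEvents` deaths are
#' present. A multivariate model (tumor size, lymph-node status, metastatic
#' status as ordinal integers; AURKA log-expression as a continuous
#' covariate) is additionally fitted when at least `minCovPatients` patients
#' have at least `minCovAvailable` of the four covariates recorded.
#' Ineligible cells are simply absent from the grid (blanks, not zeros).
#'
#' @param expr Gene-by-sample matrix.
#' @param ann Annotation data.frame with `cancer_type`, `tp53_status`,
#'   `os_time`, `os_event` and the covariate columns.
#' @param queryGene Query gene symbol.
#' @param strata Subset of `c("ALL", "WT", "MUT")`.
#' @param covariateCols The four adjustment covariates.
#' @param minEvents Univariate gate (default 10 events).
#' @param minCovPatients,minCovAvailable Multivariate gate (default: >= 3 of
#'   the 4 covariates present for >= 20 patients).
#' @param ties Tie correction for [coxFit()].
#' @param alpha Significance mark threshold (default 0.05).
#' @return data.frame grid with one row per fitted (cancer type, stratum,
#'   model) cell: `N`, `n_events`, `HR`, `ci_lo`, `ci_hi`, `p`, `significant`.
#' @export
survivalScreen <- function(expr, ann, queryGene,
                           strata = c("ALL", "WT", "MUT"),
                           covariateCols = c("size_stage", "node_stage",
                                             "met_stage", "AURKA"),
                           minEvents = 10, minCovPatients = 20,
                           minCovAvailable = 3, ties = "efron",
                           alpha = 0.05) {
  stopifnot(queryGene %in% rownames(expr))
  rows <- list()
  for (ct in unique(ann$cancer_type)) {
    for (st in strata) {
      sub <- ann[ann$cancer_type == ct, , drop = FALSE]
      if (st != "ALL")
        sub <- sub[!is.na(sub$tp53_status) & sub$tp53_status == st, ,
                   drop = FALSE]
      sub <- sub[!is.na(sub$os_time) & !is.na(sub$os_event), , drop = FALSE]
      sub <- sub[sub$sample_id %in% colnames(expr), , drop = FALSE]
      if (nrow(sub) < 4L) next
      q <- expr[queryGene, sub$sample_id]
      grp <- tryCatch(dichotomizeByMedian(q), error = function(e) NULL)
      if (is.null(grp)) next
      if (sum(sub$os_event) >= minEvents) {
        uni <- coxFit(data.frame(query_high = grp), sub$os_time,
                      sub$os_event, ties = ties)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(cancer_type = ct, stratum = st, model = "univariate",
                     stringsAsFactors = FALSE), uni)
        covPresent <- intersect(covariateCols, names(sub))
        nAvail <- if (length(covPresent))
          rowSums(!is.na(sub[, covPresent, drop = FALSE])) else 0
        if (sum(nAvail >= minCovAvailable) >= minCovPatients) {
          covDf <- data.frame(query_high = grp)
          for (cv in covPresent) covDf[[cv]] <- sub[[cv]]
          multi <- coxFit(covDf, sub$os_time, sub$os_event, ties = ties)
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(cancer_type = ct, stratum = st,
                       model = "multivariate", stringsAsFactors = FALSE),
            multi)
        }
      }
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}
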
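test_that("median dichotomization sends ties low", {
  expect_equal(as.character(dichotomizeByMedian(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(dichotomizeByMedian(c(1, 2, 3))),
               c("low", "low", "high"))
  expect_error(dichotomizeByMedian(rep(5, 4)), "impossible")
  expect_error(dichotomizeByMedian(c(1, 2, 2, 2)), "impossible")
  # brute-force oracle on random vectors
  set.seed(14)
  for (i in 1:20) {
    v <- rnorm(sample(5:30, 1))
    lab <- dichotomizeByMedian(v)
    expect_identical(lab == "low", v <= median(v))
  }
})

test_that("log-rank matches a hand-computed hypergeometric statistic", {
  # identical groups duplicated: statistic 0, p = 1
  t0 <- c(3, 6, 9, 3, 6, 9)
  g0 <- rep(c("a", "b"), each = 3)
  r0 <- kmLogrank(t0, rep(TRUE, 6), g0)
  expect_equal(r0$chisq, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-12)

  # six subjects, all events, 3/3 split: hand enumeration of O-E and V
  times <- c(6, 7, 10, 15, 19, 25)
  grp <- rep(c("a", "b"), each = 3)
  oMinusE <- 0; v <- 0
  for (tm in sort(times)) {
    atRisk <- times >= tm
    n <- sum(atRisk); n1 <- sum(atRisk & grp == "a")
    d <- sum(times == tm)
    d1 <- sum(times == tm & grp == "a")
    oMinusE <- oMinusE + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chiHand <- oMinusE^2 / v
  r <- kmLogrank(times, rep(TRUE, 6), grp)
  expect_equal(r$chisq, chiHand, tolerance = 1e-9)

  expect_error(kmLogrank(times, rep(FALSE, 6), grp), "event")
  expect_error(kmLogrank(times, rep(TRUE, 6), rep("a", 6)), "two groups")
})

test_that("a strong planted hazard is detected by the log-rank test", {
  spec <- syntheticSpec(
    cancerTypes = data.frame(acronym = "AA", n_samples = 500,
                             log_hr = log(2), censor_rate = 0.3),
    nGenes = 50, seed = 23)
  sim <- generateCohort(spec)
  a <- sim$annotations
  grp <- dichotomizeByMedian(sim$expr["QGENE", a$sample_id])
  r <- kmLogrank(a$os_time, a$os_event, grp)
  expect_lt(r$p, 0.01)
})

test_that("Cox HR matches the closed-form exponential rate-ratio oracle", {
  set.seed(19)
  n <- 1000
  grp <- rep(c(0, 1), each = n)
  tt <- c(rexp(n, 1), rexp(n, 0.5))
  closed <- (sum(grp == 1) / sum(tt[grp == 1])) /
    (sum(grp == 0) / sum(tt[grp == 0]))
  fit <- coxFit(data.frame(g = factor(grp)), tt, rep(TRUE, 2 * n))
  expect_equal(fit$HR, closed, tolerance = 0.05)
  # null group indicator stays near HR 1
  set.seed(20)
  gN <- factor(rbinom(1000, 1, 0.5))
  tN <- rexp(1000, 1)
  fN <- coxFit(data.frame(g = gN), tN, rep(TRUE, 1000))
  expect_gt(fN$HR, 0.8); expect_lt(fN$HR, 1.25)
})

test_that("Cox fit is time-scale invariant and tie-method consistent", {
  set.seed(21)
  n <- 300
  g <- factor(rbinom(n, 1, 0.5))
  tt <- rexp(n, ifelse(g == 1, 0.5, 1))
  ev <- runif(n) > 0.2
  f1 <- coxFit(data.frame(g = g), tt, ev)
  f2 <- coxFit(data.frame(g = g), tt * 365.25, ev)
  expect_equal(f1$HR, f2$HR, tolerance = 1e-9)
  expect_equal(f1$p, f2$p, tolerance = 1e-9)
  # continuous times: Efron and Breslow coincide
  fB <- coxFit(data.frame(g = g), tt, ev, ties = "breslow")
  expect_equal(log(f1$HR), log(fB$HR), tolerance = 1e-8)
})

test_that("complete separation is flagged, not thrown", {
  g <- factor(rep(c("low", "high"), each = 10), levels = c("low", "high"))
  tt <- c(101:110, 1:10)  # all 'high' die before any 'low'
  fit <- coxFit(data.frame(g = g), tt, rep(TRUE, 20))
  expect_false(fit$converged)
  expect_true(is.na(fit$HR))
})

test_that("survival screen applies the event and covariate gates", {
  set.seed(33)
  mkCohort <- function(n, nEvents, nCovPatients) {
    ann <- data.frame(
      sample_id = paste0("s", 1:n), cancer_type = "X",
      tp53_status = "WT",
      os_time = runif(n, 100, 1000),
      os_event = c(rep(TRUE, nEvents), rep(FALSE, n - nEvents)),
      size_stage = NA_real_, node_stage = NA_real_, met_stage = NA_real_,
      AURKA = NA_real_, stringsAsFactors = FALSE)
    ok <- seq_len(nCovPatients)
    ann$size_stage[ok] <- 1; ann$node_stage[ok] <- 1; ann$AURKA[ok] <- rnorm(
      nCovPatients)
    expr <- matrix(rnorm(n), 1, n, dimnames = list("Q", ann$sample_id))
    list(expr = expr, ann = ann)
  }
  # 9 events: no univariate (or multivariate) cell at all
  few <- mkCohort(40, 9, 40)
  expect_equal(nrow(survivalScreen(few$expr, few$ann, "Q",
                                   strata = "ALL")), 0L)
  # 19 covariate-complete patients: univariate only
  g19 <- mkCohort(60, 30, 19)
  out19 <- survivalScreen(g19$expr, g19$ann, "Q", strata = "ALL")
  expect_equal(out19$model, "univariate")
  # 20 covariate-complete patients: multivariate appears
  g20 <- mkCohort(60, 30, 20)
  out20 <- survivalScreen(g20$expr, g20$ann, "Q", strata = "ALL")
  expect_setequal(out20$model, c("univariate", "multivariate"))
})

test_that("screen recovers a planted protective hazard with covariates", {
  spec <- syntheticSpec(
    cancerTypes = data.frame(acronym = "AA", n_samples = 800, log_hr = -1,
                             censor_rate = 0.3),
    nGenes = 60, seed = 29)
  sim <- generateCohort(spec)
  out <- survivalScreen(sim$expr, sim$annotations, "QGENE", strata = "ALL")
  multi <- out[out$model == "multivariate", ]
  expect_equal(nrow(multi), 1L)
  expect_gte(multi$n_events, 200)
  expect_lt(multi$HR, 1)
  expect_lt(multi$p, 0.05)
  uni <- out[out$model == "univariate", ]
  # log-rank and univariate Cox agree in rejection at the 5% level here
  grp <- dichotomizeByMedian(sim$expr["QGENE", sim$annotations$sample_id])
  lr <- kmLogrank(sim$annotations$os_time, sim$annotations$os_event, grp)
  expect_equal(lr$p < 0.05, uni$p < 0.05)
})
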
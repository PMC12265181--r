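specFull <- mimicSpec(predictors = c("ses_z", "age_z", "sex_z"))

test_that("specification construction and validity", {
  spec <- mimicSpec()
  expect_s4_class(spec, "MimicSpec")
  expect_length(spec@indicators, 11L)
  expect_error(mimicSpec(residualCov = list(c("dg", "nope"))),
               "must name indicators")
  expect_error(mimicSpec(residualCov = list(c("dg", "a68"),
                                            c("a68", "dg"))),
               "distinct")
  expect_false(cfaSpec(spec)@structural)
})

test_that("model-implied covariance follows the factor algebra", {
  spec2 <- mimicSpec(indicators = c("y1", "y2"), predictors = character(0),
                     residualCov = list(), structural = FALSE)
  # all loadings zero: Sigma_yy = Theta
  th0 <- list(lambda = c(0, 0), gamma = numeric(0), psi = 4,
              theta = diag(c(2, 3)), phi = matrix(numeric(0), 0, 0))
  expect_equal(unname(modelImpliedCov(spec2, th0)), diag(c(2, 3)))
  # hand algebra: lambda = (1, .5), psi = 4, Theta = I
  th1 <- list(lambda = c(1, 0.5), gamma = numeric(0), psi = 4,
              theta = diag(2), phi = matrix(numeric(0), 0, 0))
  expect_equal(unname(modelImpliedCov(spec2, th1)),
               matrix(c(5, 2, 2, 2), 2, 2))
  expect_error(modelImpliedCov(spec2, list(lambda = 1, gamma = numeric(0),
                                           psi = 1, theta = diag(2))),
               "one entry per indicator")
})

test_that("implied covariance matches a generate-and-covary simulation", {
  spec3 <- mimicSpec(indicators = c("y1", "y2", "y3"),
                     predictors = c("x1", "x2"),
                     residualCov = list(c("y1", "y2")))
  lam <- c(1, 0.8, 0.6); gam <- c(0.5, -0.3); psi <- 0.7
  Theta <- diag(c(0.5, 0.6, 0.7)); Theta[1, 2] <- Theta[2, 1] <- 0.15
  phi <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  th <- list(lambda = lam, gamma = gam, psi = psi, theta = Theta,
             phi = phi)
  Sig <- modelImpliedCov(spec3, th)
  set.seed(99)
  n <- 200000
  X <- matrix(rnorm(2 * n), n) %*% chol(phi)
  ga <- drop(X %*% gam) + rnorm(n, 0, sqrt(psi))
  Y <- outer(ga, lam) + matrix(rnorm(3 * n), n) %*% chol(Theta)
  emp <- cov(cbind(Y, X))
  expect_lt(max(abs(emp - Sig)), 0.02)
})

test_that("degrees of freedom arithmetic matches hand counts", {
  expect_identical(semDf(specFull), 70L)          # 105 - (29 + 6)
  expect_identical(semDf(cfaSpec(specFull)), 40L) # 66 - 26
  # a 3-indicator CFA without residual covariances is saturated
  s3 <- mimicSpec(indicators = c("y1", "y2", "y3"),
                  predictors = character(0), residualCov = list(),
                  structural = FALSE)
  expect_identical(semDf(s3), 0L)
  # a 2-indicator model has more parameters than moments
  s2 <- mimicSpec(indicators = c("y1", "y2"), predictors = character(0),
                  residualCov = list(), structural = FALSE)
  expect_error(semDf(s2), "over-parameterized")
})

test_that("fitting exact population moments recovers the truth exactly", {
  pm <- populationMoments(n = 500)
  fit <- fitMimic(specFull, moments = pm)
  expect_true(fit@converged)
  expect_lt(fit@fmin, 1e-10)
  expect_lt(fit@chisq, 1e-6)
  truth <- generatingFreeParams(specFull)
  expect_lt(max(abs(coef(fit) - truth)), 1e-6)
  # perfect-fit limit of the indices
  ind <- fitIndices(fit)
  expect_equal(ind$cfi, 1)
  expect_equal(ind$rmsea, 0)
  # and the same holds for the CFA step
  cfa <- fitMimic(cfaSpec(specFull), moments = pm)
  expect_lt(max(abs(coef(cfa) - generatingFreeParams(cfaSpec(specFull)))),
            1e-6)
})

test_that("estimates agree with a generic optimizer of the discrepancy", {
  spec4 <- mimicSpec(indicators = c("y1", "y2", "y3", "y4"),
                     predictors = character(0), residualCov = list(),
                     structural = FALSE)
  set.seed(17)
  n <- 300
  ga <- rnorm(n)
  lamT <- c(1, 0.9, 0.7, 0.5)
  Y <- outer(ga, lamT) + matrix(rnorm(4 * n), n) %*% diag(sqrt(c(0.4, 0.5,
                                                                 0.6, 0.7)))
  colnames(Y) <- paste0("y", 1:4)
  dat <- as.data.frame(Y)
  fit <- fitMimic(spec4, dat)
  S <- cov(as.matrix(dat))
  ref <- optim(c(1, 1, 1, 1, diag(S) / 2), naiveCfaFml, S = S,
               method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  ours <- unname(coef(fit)[c("GA=~y2", "GA=~y3", "GA=~y4", "GA~~GA",
                             "y1~~y1", "y2~~y2", "y3~~y3", "y4~~y4")])
  expect_lt(max(abs(ours - ref$par)), 1e-4)
  expect_equal(fit@fmin, ref$value, tolerance = 1e-6)
})

test_that("estimates stay within three standard errors at large n", {
  coh <- simulateCohort(4000, seed = 77)
  fit <- fitMimic(specFull, coh)
  truth <- generatingFreeParams(specFull)
  expect_true(fit@converged)
  expect_false(fit@heywood)
  expect_true(all(abs(coef(fit) - truth) <= 3 * semSE(fit)))
})

test_that("fit indices match an independently coded computation", {
  coh <- simulateCohort(600, seed = 31)
  fit <- fitMimic(cfaSpec(mimicSpec()), coh)
  ind <- fitIndices(fit)
  # straight-line re-computation from the same moments
  S <- fit@moments$cov
  n <- fit@moments$n
  p <- ncol(S)
  Sig <- impliedCov(fit)
  Tm <- (n - 1) * (log(det(Sig)) - log(det(S)) +
                     sum(diag(S %*% solve(Sig))) - p)
  df <- 40
  Tb <- (n - 1) * (log(det(diag(diag(S)))) - log(det(S)))
  dfb <- p * (p + 1) / 2 - p
  cfi <- 1 - max(Tm - df, 0) / max(Tb - dfb, Tm - df, 0)
  tli <- ((Tb / dfb) - (Tm / df)) / ((Tb / dfb) - 1)
  rmsea <- sqrt(max(Tm - df, 0) / (df * (n - 1)))
  D <- (S - Sig) / sqrt(outer(diag(S), diag(S)))
  srmr <- sqrt(mean(D[upper.tri(D, diag = TRUE)]^2))
  expect_equal(ind$chisq, Tm, tolerance = 1e-6)
  expect_identical(ind$df, 40L)
  expect_equal(ind$cfi, cfi, tolerance = 0.005)
  expect_equal(ind$tli, tli, tolerance = 0.005)
  expect_equal(ind$rmsea, rmsea, tolerance = 0.005)
  expect_equal(ind$srmr, srmr, tolerance = 0.005)
  # RMSEA interval brackets the point estimate
  expect_lte(ind$rmseaCI[1], ind$rmsea)
  expect_gte(ind$rmseaCI[2], ind$rmsea)
})

test_that("RMSEA interval inversion is consistent with the chi-square", {
  rs <- rmseaStatistics(119.7, 70, 132)
  expect_equal(rs$rmsea, sqrt(49.7 / (70 * 131)), tolerance = 1e-12)
  # at the CI endpoints the noncentral distribution reproduces the levels
  lo <- rs$ci[1]^2 * 70 * 131
  hi <- rs$ci[2]^2 * 70 * 131
  expect_equal(pchisq(119.7, 70, ncp = lo), 0.95, tolerance = 1e-6)
  expect_equal(pchisq(119.7, 70, ncp = hi), 0.05, tolerance = 1e-6)
  expect_equal(rs$pClose,
               pchisq(119.7, 70, ncp = 0.05^2 * 70 * 131,
                      lower.tail = FALSE), tolerance = 1e-12)
  # df = 0 has no RMSEA
  expect_true(is.na(rmseaStatistics(0, 0, 100)$rmsea))
})

test_that("modification indices locate an omitted residual covariance", {
  gen <- cohortParams(residPairs = list(c("c94", "c104"),
                                        c("c104", "c114"),
                                        c("c114", "c124"),
                                        c("a68", "a78"),
                                        c("c84", "c94")),
                      residCov = c(0.1, 0.1, 0.1, 0.1, 0.18))
  hits <- 0L
  for (r in 1:25) {
    coh <- simulateCohort(500, gen, seed = 400 + r)
    fit <- fitMimic(cfaSpec(mimicSpec()), coh)   # (c84, c94) omitted
    mi <- modificationIndices(fit)
    top <- sort(c(mi$lhs[1], mi$rhs[1]))
    if (identical(top, c("c84", "c94"))) hits <- hits + 1L
  }
  expect_gte(hits, 20L)   # detected in >= 80% of replicates

  # a free parameter is never listed
  fit <- fitMimic(cfaSpec(mimicSpec()), simulateCohort(500, seed = 1))
  mi <- modificationIndices(fit)
  keys <- paste(pmin(mi$lhs, mi$rhs), pmax(mi$lhs, mi$rhs))
  expect_false("c104 c94" %in% keys)
  expect_false("a68 a78" %in% keys)
  expect_equal(nrow(mi), 11 * 10 / 2 - 4)
})

test_that("the top modification index approximates the refit chi-square drop", {
  gen <- cohortParams(residPairs = list(c("c94", "c104"),
                                        c("c104", "c114"),
                                        c("c114", "c124"),
                                        c("a68", "a78"),
                                        c("c84", "c94")),
                      residCov = c(0.1, 0.1, 0.1, 0.1, 0.18))
  coh <- simulateCohort(800, gen, seed = 555)
  fit <- fitMimic(cfaSpec(mimicSpec()), coh)
  mi <- modificationIndices(fit, top = 1)
  freed <- mimicSpec(residualCov = list(c("c94", "c104"),
                                        c("c104", "c114"),
                                        c("c114", "c124"),
                                        c("a68", "a78"),
                                        c(mi$lhs[1], mi$rhs[1])))
  fit2 <- fitMimic(cfaSpec(freed), coh)
  drop <- fit@chisq - fit2@chisq
  expect_lt(abs(mi$mi[1] - drop), 0.15 * mi$mi[1])
})

test_that("the standardized solution is invariant to identification", {
  coh <- simulateCohort(800, seed = 63)
  s1 <- mimicSpec(indicators = c("dg", "a68", "a78", "a88"),
                  predictors = character(0), residualCov = list(),
                  structural = FALSE)
  s2 <- mimicSpec(indicators = c("dg", "a68", "a78", "a88"),
                  predictors = character(0), residualCov = list(),
                  identification = "fix_latent_variance",
                  structural = FALSE)
  f1 <- fitMimic(s1, coh); f2 <- fitMimic(s2, coh)
  expect_lt(max(abs(standardizedSolution(f1)$std -
                      standardizedSolution(f2)$std)), 1e-6)
  # raw parameterizations differ, fitted covariance does not
  expect_lt(max(abs(impliedCov(f1) - impliedCov(f2))), 1e-5)
})

test_that("standardization at population moments returns generating values", {
  fit <- fitMimic(specFull, moments = populationMoments(n = 1000))
  std <- standardizedSolution(fit)
  gen <- cohortParams()
  expect_equal(std$std[std$type == "loading"], unname(gen$loadings),
               tolerance = 1e-4)
  expect_equal(std$std[std$type == "path"], unname(gen$paths),
               tolerance = 1e-4)
  expect_equal(std$std[std$type == "residual_cov"],
               rep(0.10, 4) / 1, tolerance = 1e-4)
})

test_that("two-step estimation reports thresholds for both steps", {
  coh <- simulateCohort(2000, seed = 19)
  spec <- mimicSpec(predictors = c("ses_z", "age_z", "sex_z"))
  ts <- twoStepFit(spec, coh)
  expect_identical(ts$cfa$fit@df, 40L)
  expect_identical(ts$structural$fit@df, 70L)
  expect_true(all(ts$cfa$report$pass))       # well-specified model
  expect_true(all(ts$structural$report$pass))
  expect_error(twoStepFit(cfaSpec(spec), coh), "structural part")
})

test_that("a gross misspecification is caught by the measurement step", {
  set.seed(3)
  fails <- 0L
  for (r in 1:5) {
    n <- 2000
    gaA <- rnorm(n); gaB <- rnorm(n)   # two independent factors
    lam <- cohortParams()$loadings
    Y <- cbind(outer(gaA, lam[1:6]), outer(gaB, lam[7:11])) +
      matrix(rnorm(11 * n), n) %*% diag(sqrt(1 - lam^2))
    colnames(Y) <- names(lam)
    fit <- fitMimic(cfaSpec(mimicSpec()), as.data.frame(Y))
    if (fitIndices(fit)$rmsea > 0.08) fails <- fails + 1L
  }
  expect_gte(fails, 5L)
})

test_that("fitting rejects bad inputs loudly", {
  spec <- mimicSpec()
  expect_error(fitMimic(spec), "'data' or 'moments'")
  coh <- simulateCohort(8, seed = 2)
  expect_error(fitMimic(cfaSpec(spec), coh), "n > number")
  # singular sample covariance (duplicated indicator)
  coh2 <- simulateCohort(100, seed = 2)
  coh2$a68 <- coh2$dg
  expect_error(fitMimic(cfaSpec(spec), coh2), "not positive definite")
})
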
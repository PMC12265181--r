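## MIMIC / CFA covariance-structure modeling by maximum likelihood.
##
## Model: indicators y (p_y of them), predictors x (q of them, optional).
##   GA = gamma' x + zeta,        Var(zeta) = psi
##   y  = Lambda GA + eps,        Cov(eps) = Theta (diagonal + selected
##                                            off-diagonal pairs)
## Implied covariance over z = (y, x):
##   Var(GA)  = gamma' Phi gamma + psi
##   Sigma_yy = Lambda Var(GA) Lambda' + Theta
##   Sigma_yx = Lambda (Phi gamma)'
##   Sigma_xx = Phi
## The exogenous block Phi is a set of parameters fitted exactly at the
## sample values (fixed-x convention); its q(q+1)/2 moments count as free
## parameters in the degrees of freedom.

#' Construct a MIMIC model specification
#'
#' @param indicators ordered character vector of indicator names; default
#'   the 11 slice asymmetry indices.
#' @param latent latent factor name.
#' @param predictors observed causes of the latent factor; default
#'   `c("ses", "age", "sex")`.
#' @param residualCov list of length-2 character vectors (indicator pairs
#'   whose residuals covary); default the four adjacent-slice pairs
#'   `(c94, c104)`, `(c104, c114)`, `(c114, c124)`, `(a68, a78)`.
#' @param identification `"fix_first_loading"` (default) or
#'   `"fix_latent_variance"`.
#' @param structural fit the structural regressions (`TRUE`) or the
#'   measurement model only (`FALSE`, CFA).
#' @return a [MimicSpec-class].
#' @examples
#' spec <- mimicSpec()
#' semDf(spec)          # 70 for the full model
#' semDf(cfaSpec(spec)) # 40 for the measurement model alone
#' @export
mimicSpec <- function(indicators = .INDICATORS, latent = "GA",
                      predictors = c("ses", "age", "sex"),
                      residualCov = list(c("c94", "c104"),
                                         c("c104", "c114"),
                                         c("c114", "c124"),
                                         c("a68", "a78")),
                      identification = c("fix_first_loading",
                                         "fix_latent_variance"),
                      structural = length(predictors) > 0L) {
  identification <- match.arg(identification)
  rc <- if (length(residualCov))
    do.call(rbind, lapply(residualCov, function(p) matrix(p, 1L, 2L)))
  else matrix(character(0), 0L, 2L)
  new("MimicSpec", indicators = indicators, latent = latent,
      predictors = predictors, residualCov = rc,
      identification = identification, structural = structural)
}

#' @describeIn mimicSpec the same specification with the structural part
#'   switched off (step 1 of the two-step procedure).
#' @param spec a `MimicSpec`.
#' @export
cfaSpec <- function(spec) {
  new("MimicSpec", indicators = spec@indicators, latent = spec@latent,
      predictors = spec@predictors, residualCov = spec@residualCov,
      identification = spec@identification, structural = FALSE)
}

setMethod("show", "MimicSpec", function(object) {
  cat("MimicSpec: latent '", object@latent, "' measured by ",
      length(object@indicators), " indicators\n", sep = "")
  if (object@structural)
    cat("  regressed on: ", paste(object@predictors, collapse = ", "),
        "\n", sep = "")
  else cat("  measurement model only (CFA)\n")
  if (nrow(object@residualCov))
    cat("  residual covariances: ",
        paste(apply(object@residualCov, 1L, paste, collapse = "~~"),
              collapse = ", "), "\n", sep = "")
  cat("  identification: ", object@identification, "\n", sep = "")
})

## ---- free-parameter bookkeeping -------------------------------------

## rows: type in {lambda, gamma, psi, theta_d, theta_o}; i, j are indicator
## or predictor indices
.paramTable <- function(spec) {
  py <- length(spec@indicators)
  fixFirst <- spec@identification == "fix_first_loading"
  lamIdx <- if (fixFirst) seq_len(py)[-1L] else seq_len(py)
  tab <- data.frame(type = "lambda", i = lamIdx, j = 0L,
                    label = paste0(spec@latent, "=~",
                                   spec@indicators[lamIdx]))
  if (spec@structural) {
    q <- length(spec@predictors)
    tab <- rbind(tab, data.frame(type = "gamma", i = seq_len(q), j = 0L,
                                 label = paste0(spec@latent, "~",
                                                spec@predictors)))
  }
  if (fixFirst)
    tab <- rbind(tab, data.frame(type = "psi", i = 0L, j = 0L,
                                 label = paste0(spec@latent, "~~",
                                                spec@latent)))
  tab <- rbind(tab, data.frame(type = "theta_d", i = seq_len(py), j = 0L,
                               label = paste0(spec@indicators, "~~",
                                              spec@indicators)))
  if (nrow(spec@residualCov)) {
    ii <- match(spec@residualCov[, 1L], spec@indicators)
    jj <- match(spec@residualCov[, 2L], spec@indicators)
    tab <- rbind(tab, data.frame(type = "theta_o", i = ii, j = jj,
                                 label = paste0(spec@residualCov[, 1L],
                                                "~~",
                                                spec@residualCov[, 2L])))
  }
  rownames(tab) <- NULL
  tab
}

#' Degrees of freedom of a MIMIC / CFA specification
#'
#' Unique sample moments `p(p+1)/2` minus the number of free or
#' exactly-fitted parameters: free loadings, structural paths, the latent
#' disturbance variance, indicator residual (co)variances, and the
#' exogenous variance/covariance block (counted as exactly fitted). The
#' default full specification (11 indicators, 3 predictors, 4 residual
#' covariances, first loading fixed) gives 70; its CFA gives 40.
#'
#' @param spec a [MimicSpec-class].
#' @return integer degrees of freedom.
#' @export
semDf <- function(spec) {
  py <- length(spec@indicators)
  q <- if (spec@structural) length(spec@predictors) else 0L
  p <- py + q
  nFree <- nrow(.paramTable(spec)) + (q * (q + 1L)) %/% 2L
  df <- (p * (p + 1L)) %/% 2L - nFree
  if (df < 0L)
    stop("over-parameterized specification: df = ", df, call. = FALSE)
  as.integer(df)
}

## full parameter matrices from the free vector
.thetaFromFree <- function(spec, free, phi) {
  tab <- .paramTable(spec)
  py <- length(spec@indicators)
  lambda <- rep(1, py)
  w <- tab$type == "lambda"
  lambda[tab$i[w]] <- free[w]
  gamma <- if (spec@structural) free[tab$type == "gamma"] else numeric(0)
  psi <- if (spec@identification == "fix_first_loading")
    free[tab$type == "psi"] else 1
  Theta <- matrix(0, py, py)
  w <- tab$type == "theta_d"
  diag(Theta)[tab$i[w]] <- free[w]
  w <- which(tab$type == "theta_o")
  for (k in w) Theta[tab$i[k], tab$j[k]] <- Theta[tab$j[k], tab$i[k]] <-
      free[k]
  varLatent <- psi + if (spec@structural && length(gamma))
    drop(crossprod(gamma, phi %*% gamma)) else 0
  list(lambda = lambda, gamma = gamma, psi = psi, theta = Theta,
       phi = phi, varLatent = varLatent)
}

## free vector from full parameter values (used for start values and to
## map generating parameters onto the fitted parameterization)
.freeFromTheta <- function(spec, lambda, gamma, psi, Theta) {
  tab <- .paramTable(spec)
  free <- numeric(nrow(tab))
  for (k in seq_len(nrow(tab)))
    free[k] <- switch(tab$type[k],
      lambda = lambda[tab$i[k]],
      gamma = gamma[tab$i[k]],
      psi = psi,
      theta_d = Theta[tab$i[k], tab$i[k]],
      theta_o = Theta[tab$i[k], tab$j[k]])
  names(free) <- tab$label
  free
}

#' Model-implied covariance matrix
#'
#' Covariance matrix over all modeled observed variables (indicators, then
#' predictors when the structural part is on) implied by a full parameter
#' set.
#'
#' @param spec a [MimicSpec-class].
#' @param theta list with `lambda` (full loading vector), `gamma`
#'   (structural paths, may be empty), `psi` (latent disturbance variance),
#'   `theta` (indicator residual covariance matrix), `phi` (exogenous
#'   covariance block).
#' @return symmetric covariance matrix with dimnames.
#' @export
modelImpliedCov <- function(spec, theta) {
  py <- length(spec@indicators)
  lambda <- theta$lambda
  if (length(lambda) != py)
    stop("'lambda' must have one entry per indicator", call. = FALSE)
  Theta <- theta$theta
  if (!identical(dim(Theta), c(py, py)))
    stop("'theta' residual matrix has the wrong shape", call. = FALSE)
  if (spec@structural) {
    q <- length(spec@predictors)
    gamma <- theta$gamma; phi <- theta$phi
    if (length(gamma) != q || !identical(dim(phi), c(q, q)))
      stop("'gamma'/'phi' not conformable with the predictors",
           call. = FALSE)
    v <- theta$psi + drop(crossprod(gamma, phi %*% gamma))
    Syy <- v * tcrossprod(lambda) + Theta
    Syx <- tcrossprod(lambda, drop(phi %*% gamma))
    Sig <- rbind(cbind(Syy, Syx), cbind(t(Syx), phi))
    nm <- c(spec@indicators, spec@predictors)
  } else {
    Sig <- theta$psi * tcrossprod(lambda) + Theta
    nm <- spec@indicators
  }
  dimnames(Sig) <- list(nm, nm)
  Sig
}

## dSigma/dtheta_k for every free parameter, as dense p x p matrices
.sigmaDerivs <- function(spec, th) {
  tab <- .paramTable(spec)
  py <- length(spec@indicators)
  q <- if (spec@structural) length(spec@predictors) else 0L
  p <- py + q
  lambda <- th$lambda; v <- th$varLatent
  phiGamma <- if (q) drop(th$phi %*% th$gamma) else numeric(0)
  out <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    D <- matrix(0, p, p)
    i <- tab$i[k]; j <- tab$j[k]
    switch(tab$type[k],
      lambda = {
        D[i, seq_len(py)] <- D[i, seq_len(py)] + v * lambda
        D[seq_len(py), i] <- D[seq_len(py), i] + v * lambda
        if (q) {
          D[i, py + seq_len(q)] <- phiGamma
          D[py + seq_len(q), i] <- phiGamma
        }
      },
      gamma = {
        dv <- 2 * phiGamma[i]
        D[seq_len(py), seq_len(py)] <- dv * tcrossprod(lambda)
        D[seq_len(py), py + seq_len(q)] <-
          tcrossprod(lambda, th$phi[, i])
        D[py + seq_len(q), seq_len(py)] <-
          t(D[seq_len(py), py + seq_len(q)])
      },
      psi = {
        D[seq_len(py), seq_len(py)] <- tcrossprod(lambda)
      },
      theta_d = { D[i, i] <- 1 },
      theta_o = { D[i, j] <- D[j, i] <- 1 })
    out[[k]] <- D
  }
  out
}

## ML discrepancy; returns NA when Sigma is not positive definite
.fml <- function(S, Sigma, logDetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(list(f = NA_real_))
  logDet <- 2 * sum(log(diag(ch)))
  SigInv <- chol2inv(ch)
  f <- logDet - logDetS + sum(S * SigInv) - nrow(S)
  list(f = f, SigInv = SigInv)
}

#' Sample moments for covariance-structure fitting
#'
#' @param data data.frame containing the variables.
#' @param vars character vector of variable names (order defines the
#'   moment order).
#' @return list with `cov` (divisor `n - 1`), `means`, `n`, `names`.
#' @export
sampleMoments <- function(data, vars) {
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("variables not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- data[, vars, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]   # listwise deletion
  n <- nrow(X)
  if (n <= length(vars))
    stop("need n > number of modeled variables (n = ", n, ")",
         call. = FALSE)
  list(cov = stats::cov(as.matrix(X)), means = colMeans(as.matrix(X)),
       n = n, names = vars)
}

#' @describeIn sampleMoments wrap a known covariance matrix (e.g. exact
#'   population moments) for fitting.
#' @param cov symmetric covariance matrix with dimnames.
#' @param n nominal sample size.
#' @param means optional mean vector (defaults to zero).
#' @export
momentsFromCov <- function(cov, n, means = NULL) {
  nm <- colnames(cov)
  if (is.null(nm)) stop("'cov' needs dimnames", call. = FALSE)
  if (is.null(means)) means <- setNames(rep(0, ncol(cov)), nm)
  list(cov = cov, means = means, n = as.integer(n), names = nm)
}

.momentsFor <- function(moments, vars) {
  idx <- match(vars, moments$names)
  if (anyNA(idx))
    stop("moments lack variables: ",
         paste(vars[is.na(idx)], collapse = ", "), call. = FALSE)
  list(cov = moments$cov[idx, idx, drop = FALSE],
       means = moments$means[idx], n = moments$n, names = vars)
}

## ---- estimation ------------------------------------------------------

.startValues <- function(spec, S) {
  py <- length(spec@indicators)
  Syy <- S[seq_len(py), seq_len(py), drop = FALSE]
  e <- eigen(Syy, symmetric = TRUE)
  v1 <- e$vectors[, 1L] * sqrt(max(e$values[1L], 1e-8))
  if (sum(v1) < 0) v1 <- -v1
  v1[abs(v1) < 1e-6] <- 1e-6
  Theta0 <- diag(pmax(diag(Syy) / 2, 1e-6), py)
  if (spec@identification == "fix_first_loading") {
    lambda0 <- v1 / v1[1L]
    psi0 <- v1[1L]^2
  } else {
    lambda0 <- v1
    psi0 <- 1
  }
  gamma0 <- if (spec@structural) rep(0, length(spec@predictors))
            else numeric(0)
  .freeFromTheta(spec, lambda0, gamma0, psi0, Theta0)
}

#' Fit a MIMIC / CFA model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F(theta) = log det Sigma(theta) - log det S + tr(S Sigma(theta)^-1) - p`
#' over the free parameters with an analytic gradient (quasi-Newton,
#' deterministic start from the first principal axis of the indicator
#' covariance). The chi-square statistic is `(n - 1) * F` at the minimum;
#' standard errors come from the inverse expected information. The
#' exogenous predictor block is fitted exactly at its sample values.
#'
#' Non-convergence is flagged on the returned object, never silent; a
#' negative variance estimate (Heywood case) sets the `heywood` flag with a
#' warning.
#'
#' @param spec a [MimicSpec-class].
#' @param data data.frame with the indicator and predictor columns
#'   (rows with missing values are dropped listwise), or `NULL` when
#'   `moments` is given.
#' @param moments precomputed [sampleMoments()] / [momentsFromCov()] list.
#' @param start optional named start vector overriding the default.
#' @param control passed to [stats::nlminb()].
#' @return a [SemFit-class].
#' @examples
#' cohort <- simulateCohort(400, seed = 1)
#' fit <- fitMimic(mimicSpec(predictors = c("ses_z", "age_z", "sex_z")),
#'                 cohort)
#' fit
#' @export
fitMimic <- function(spec, data = NULL, moments = NULL, start = NULL,
                     control = list(iter.max = 1000L, eval.max = 2000L,
                                    rel.tol = 1e-12)) {
  vars <- c(spec@indicators,
            if (spec@structural) spec@predictors else character(0))
  if (is.null(moments)) {
    if (is.null(data)) stop("give 'data' or 'moments'", call. = FALSE)
    moments <- sampleMoments(data, vars)
  } else moments <- .momentsFor(moments, vars)
  S <- moments$cov
  p <- length(vars)
  chS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(chS))
    stop("sample covariance matrix is not positive definite",
         call. = FALSE)
  logDetS <- 2 * sum(log(diag(chS)))
  py <- length(spec@indicators)
  phi <- if (spec@structural)
    S[py + seq_len(p - py), py + seq_len(p - py), drop = FALSE]
  else matrix(numeric(0), 0L, 0L)

  ## optimize on the correlation-scaled covariance: F_ML is invariant to
  ## diagonal rescaling, and unit-variance scaling keeps the problem
  ## well-conditioned when indicators live on very different (or very
  ## small) scales. Estimates are mapped back to the raw metric below.
  d <- sqrt(diag(S))
  Ssc <- S / tcrossprod(d)
  logDetSsc <- 2 * sum(log(diag(chol(Ssc))))
  phiSc <- if (spec@structural)
    Ssc[py + seq_len(p - py), py + seq_len(p - py), drop = FALSE]
  else phi
  scaleFactors <- local({
    tab <- .paramTable(spec)
    dy <- d[seq_len(py)]
    dx <- if (spec@structural) d[py + seq_len(p - py)] else numeric(0)
    ref <- if (spec@identification == "fix_first_loading") dy[1L] else 1
    vapply(seq_len(nrow(tab)), function(k) switch(tab$type[k],
      lambda = dy[tab$i[k]] / ref,
      gamma = ref / dx[tab$i[k]],
      psi = ref^2,
      theta_d = dy[tab$i[k]]^2,
      theta_o = dy[tab$i[k]] * dy[tab$j[k]]), numeric(1))
  })
  if (is.null(start)) start <- .startValues(spec, Ssc)
  else start <- start / scaleFactors
  obj <- function(free) {
    th <- .thetaFromFree(spec, free, phiSc)
    r <- .fml(Ssc, modelImpliedCov(spec, th), logDetSsc)
    if (is.na(r$f)) 1e10 else r$f
  }
  grad <- function(free) {
    th <- .thetaFromFree(spec, free, phiSc)
    Sigma <- modelImpliedCov(spec, th)
    r <- .fml(Ssc, Sigma, logDetSsc)
    if (is.na(r$f)) return(rep(0, length(free)))
    W <- r$SigInv - r$SigInv %*% Ssc %*% r$SigInv
    vapply(.sigmaDerivs(spec, th), function(D) sum(W * D), numeric(1))
  }
  opt <- stats::nlminb(start, obj, gradient = grad, control = control)
  gmax <- max(abs(grad(opt$par)))
  if (opt$convergence != 0 && gmax > 1e-6) {  # one deterministic restart
    opt2 <- stats::nlminb(opt$par, obj, gradient = grad, control = control)
    if (opt2$objective <= opt$objective) opt <- opt2
    gmax <- max(abs(grad(opt$par)))
  }
  est <- setNames(opt$par * scaleFactors, names(start))  # raw metric
  th <- .thetaFromFree(spec, est, phi)
  Sigma <- modelImpliedCov(spec, th)
  r <- .fml(S, Sigma, logDetS)
  fmin <- max(r$f, 0)
  ## nlminb status codes other than 0 (e.g. "singular convergence") can
  ## still be stationary points; judge by the gradient at the optimum
  converged <- is.finite(fmin) && fmin < 1e9 &&
    (opt$convergence == 0 || gmax < 1e-5)
  if (!converged)
    warning("optimizer did not converge (", opt$message,
            ", max |gradient| = ", signif(gmax, 3), ")", call. = FALSE)
  heywood <- any(diag(th$theta) < 0) || th$psi < 0
  if (heywood)
    warning("Heywood case: negative variance estimate", call. = FALSE)

  ## expected information (in the well-conditioned scaled metric) and
  ## standard errors, mapped back through the diagonal reparameterization
  thSc <- .thetaFromFree(spec, opt$par, phiSc)
  rSc <- .fml(Ssc, modelImpliedCov(spec, thSc), logDetSsc)
  derivs <- .sigmaDerivs(spec, thSc)
  A <- lapply(derivs, function(D) rSc$SigInv %*% D)
  k <- length(est)
  E <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k)
    E[i, j] <- E[j, i] <- sum(A[[i]] * t(A[[j]]))
  V <- tryCatch(2 / (moments$n - 1) * solve(E), error = function(e) NULL)
  if (is.null(V)) {
    warning("singular information matrix; standard errors unavailable",
            call. = FALSE)
    V <- matrix(NA_real_, k, k)
  } else V <- V * tcrossprod(scaleFactors)
  se <- setNames(sqrt(pmax(diag(V), 0)), names(est))
  df <- semDf(spec)
  chisq <- (moments$n - 1) * fmin
  new("SemFit", spec = spec, est = est, se = se, vcov = V, theta = th,
      sigma = Sigma, moments = moments, fmin = fmin, chisq = chisq,
      df = df,
      pvalue = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE)
               else NA_real_,
      converged = converged, nIter = as.integer(opt$iterations),
      heywood = heywood)
}

#' @describeIn fitMimic free parameter estimates of a fit.
#' @param object,... a `SemFit` (S4 `coef` method).
#' @export
setMethod("coef", "SemFit", function(object, ...) object@est)

#' @describeIn fitMimic standard errors of the free parameters.
#' @param fit a `SemFit`.
#' @export
semSE <- function(fit) fit@se

#' @describeIn fitMimic model-implied covariance matrix at the estimate.
#' @export
impliedCov <- function(fit) fit@sigma

setMethod("show", "SemFit", function(object) {
  cat(sprintf("SemFit (%s): chisq = %.3f, df = %d, p = %.4g\n",
              if (object@spec@structural) "MIMIC" else "CFA",
              object@chisq, object@df, object@pvalue))
  cat(sprintf("  fmin = %.6g, n = %d, converged: %s%s\n", object@fmin,
              object@moments$n, object@converged,
              if (object@heywood) " [Heywood case]" else ""))
  est <- cbind(estimate = object@est, se = object@se)
  print(round(est, 4))
})

## ---- fit indices -----------------------------------------------------

#' RMSEA point estimate, confidence interval and close-fit probability
#'
#' `rmsea = sqrt(max(chisq - df, 0) / (df * (n - 1)))`. The 90% interval
#' inverts the noncentral chi-square distribution in the noncentrality
#' parameter (monotone root-finding, tolerance 1e-8); the close-fit
#' p-value is `P(X >= chisq)` for `X` noncentral chi-square with
#' `ncp = 0.05^2 * df * (n - 1)`.
#'
#' @param chisq chi-square statistic.
#' @param df model degrees of freedom.
#' @param n sample size.
#' @param level confidence level of the interval (default 0.90).
#' @return list with `rmsea`, `ci` (lower, upper), `pClose`.
#' @examples
#' rmseaStatistics(119.7, 70, 132)$rmsea   # ~0.07
#' @export
rmseaStatistics <- function(chisq, df, n, level = 0.90) {
  if (df <= 0) return(list(rmsea = NA_real_, ci = c(NA_real_, NA_real_),
                           pClose = NA_real_))
  scale <- df * (n - 1)
  rmsea <- sqrt(max(chisq - df, 0) / scale)
  alpha <- (1 - level) / 2
  solveNcp <- function(target) {
    ## far in the tails pnchisq emits precision notices that are
    ## immaterial at the 1e-8 root tolerance used here
    f <- function(ncp)
      suppressWarnings(stats::pchisq(chisq, df, ncp = ncp)) - target
    if (f(0) <= 0) return(0)
    hi <- max(chisq, 1)
    while (f(hi) > 0 && hi < 1e7) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-8)$root
  }
  lo <- solveNcp(1 - alpha)   # pchisq = 0.95 at the lower ncp
  hi <- solveNcp(alpha)
  pClose <- suppressWarnings(
    stats::pchisq(chisq, df, ncp = 0.05^2 * scale, lower.tail = FALSE))
  list(rmsea = rmsea, ci = c(sqrt(lo / scale), sqrt(hi / scale)),
       pClose = pClose)
}

## independence baseline: indicator variances free (fitted exactly),
## exogenous block kept exactly fitted; closed form
.baselineFit <- function(fit) {
  S <- fit@moments$cov
  p <- ncol(S)
  py <- length(fit@spec@indicators)
  q <- p - py
  Sb <- matrix(0, p, p)
  diag(Sb)[seq_len(py)] <- diag(S)[seq_len(py)]
  if (q) Sb[py + seq_len(q), py + seq_len(q)] <-
      S[py + seq_len(q), py + seq_len(q)]
  chS <- chol(S); chB <- chol(Sb)
  f <- 2 * sum(log(diag(chB))) - 2 * sum(log(diag(chS)))
  df <- (p * (p + 1L)) %/% 2L - py - (q * (q + 1L)) %/% 2L
  list(chisq = (fit@moments$n - 1) * f, df = as.integer(df))
}

#' Fit indices of a fitted model
#'
#' Chi-square with p-value, CFI and TLI against the independence baseline
#' (all modeled variables uncorrelated, with the exogenous block kept
#' exactly fitted), RMSEA with 90% CI and close-fit probability, and SRMR
#' (root mean squared standardized covariance residual over the unique
#' elements).
#'
#' @param fit a [SemFit-class].
#' @param baseline optional list with `chisq` and `df` of a baseline fit;
#'   computed internally when omitted.
#' @return list of class `"semFitIndices"`.
#' @export
fitIndices <- function(fit, baseline = NULL) {
  if (is.null(baseline)) baseline <- .baselineFit(fit)
  T <- fit@chisq; df <- fit@df
  Tb <- baseline$chisq; dfb <- baseline$df
  d <- max(T - df, 0)
  db <- max(Tb - dfb, 0)
  cfi <- 1 - d / max(db, d, .Machine$double.eps)
  tli <- if (df > 0 && dfb > 0 && Tb / dfb > 1)
    ((Tb / dfb) - (T / df)) / ((Tb / dfb) - 1) else NA_real_
  rm <- rmseaStatistics(T, df, fit@moments$n)
  S <- fit@moments$cov; Sig <- fit@sigma
  sd <- sqrt(diag(S))
  R <- (S - Sig) / tcrossprod(sd)
  srmr <- sqrt(mean(R[upper.tri(R, diag = TRUE)]^2))
  structure(list(chisq = T, df = df, pvalue = fit@pvalue,
                 baselineChisq = Tb, baselineDf = dfb,
                 cfi = min(max(cfi, 0), 1), tli = tli,
                 rmsea = rm$rmsea, rmseaCI = rm$ci, pClose = rm$pClose,
                 srmr = srmr),
            class = "semFitIndices")
}

#' @export
print.semFitIndices <- function(x, ...) {
  cat(sprintf("chisq = %.3f (df = %d), p = %.4g\n", x$chisq, x$df,
              x$pvalue))
  cat(sprintf("CFI = %.3f  TLI = %.3f  SRMR = %.3f\n", x$cfi, x$tli,
              x$srmr))
  cat(sprintf("RMSEA = %.3f  90%% CI [%.3f, %.3f]  p(RMSEA <= .05) = %.3f\n",
              x$rmsea, x$rmseaCI[1], x$rmseaCI[2], x$pClose))
  invisible(x)
}

## ---- modification indices -------------------------------------------

#' Modification indices for fixed residual covariances
#'
#' Univariate score tests: for every indicator pair whose residual
#' covariance is fixed at zero, the expected chi-square drop (MI) from
#' freeing that single parameter, with the expected parameter change (EPC).
#' Pairs whose partialed information is numerically singular are returned
#' with `NA` and flagged, never fabricated.
#'
#' @param fit a converged [SemFit-class].
#' @param top return only the `top` largest entries (default all).
#' @return data.frame with columns `lhs`, `rhs`, `mi`, `epc`, sorted by
#'   decreasing MI.
#' @export
modificationIndices <- function(fit, top = Inf) {
  if (!fit@converged)
    stop("modification indices need a converged fit", call. = FALSE)
  spec <- fit@spec
  py <- length(spec@indicators)
  ## work in the correlation-scaled metric (score tests are invariant to
  ## diagonal rescaling; the scaled problem is well-conditioned)
  d <- sqrt(diag(fit@moments$cov))
  S <- fit@moments$cov / tcrossprod(d)
  Sigma <- fit@sigma / tcrossprod(d)
  th <- fit@theta
  ref <- if (spec@identification == "fix_first_loading")
    d[1L] else 1
  dy <- d[seq_len(py)]
  thSc <- list(
    lambda = th$lambda * ref / dy,
    gamma = if (length(th$gamma))
      th$gamma * d[py + seq_along(th$gamma)] / ref else th$gamma,
    psi = th$psi / ref^2,
    theta = th$theta / tcrossprod(dy),
    phi = if (length(th$phi))
      th$phi / tcrossprod(d[py + seq_len(ncol(th$phi))]) else th$phi)
  thSc$varLatent <- th$varLatent / ref^2
  ch <- chol(Sigma); SigInv <- chol2inv(ch)
  W <- SigInv - SigInv %*% S %*% SigInv
  derivs <- .sigmaDerivs(spec, thSc)
  A <- lapply(derivs, function(D) SigInv %*% D)
  k <- length(derivs)
  E <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k)
    E[i, j] <- E[j, i] <- sum(A[[i]] * t(A[[j]]))
  Einv <- tryCatch(solve(E), error = function(e) NULL)
  free <- apply(spec@residualCov, 1L,
                function(p) paste(sort(p), collapse = "~~"))
  p <- ncol(Sigma)
  out <- list()
  for (i in seq_len(py - 1L)) for (j in (i + 1L):py) {
    key <- paste(sort(c(spec@indicators[i], spec@indicators[j])),
                 collapse = "~~")
    if (key %in% free) next
    D <- matrix(0, p, p); D[i, j] <- D[j, i] <- 1
    g <- sum(W * D)
    Ac <- SigInv %*% D
    Ecc <- sum(Ac * t(Ac))
    Ect <- vapply(A, function(Aj) sum(Ac * t(Aj)), numeric(1))
    part <- if (is.null(Einv)) NA_real_
            else Ecc - drop(crossprod(Ect, Einv %*% Ect))
    if (!is.finite(part) || part <= 1e-12) {
      out[[key]] <- data.frame(lhs = spec@indicators[i],
                               rhs = spec@indicators[j],
                               mi = NA_real_, epc = NA_real_)
      next
    }
    out[[key]] <- data.frame(
      lhs = spec@indicators[i], rhs = spec@indicators[j],
      mi = (fit@moments$n - 1) * g^2 / (2 * part),
      epc = -g / part * dy[i] * dy[j])   # back to the raw metric
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(-res$mi, na.last = TRUE), , drop = FALSE]
  utils::head(res, top)
}

## ---- standardized solution ------------------------------------------

#' Standardized solution of a fitted model
#'
#' Loadings rescaled to the correlation metric (latent and indicators at
#' unit variance), structural paths scaled by the predictor and latent
#' standard deviations, residual covariances as residual correlations. The
#' standardized solution is invariant to the identification constraint.
#'
#' @param fit a [SemFit-class] (converged, positive variances; a Heywood
#'   case is flagged with a warning and affected rows are `NaN`).
#' @return data.frame with columns `param`, `type`, `est`, `std`.
#' @export
standardizedSolution <- function(fit) {
  spec <- fit@spec
  th <- fit@theta
  py <- length(spec@indicators)
  if (fit@heywood)
    warning("Heywood case: standardized values unreliable",
            call. = FALSE)
  sdGA <- sqrt(th$varLatent)
  sdy <- sqrt(diag(fit@sigma)[seq_len(py)])
  rows <- data.frame(
    param = paste0(spec@latent, "=~", spec@indicators),
    type = "loading",
    est = th$lambda,
    std = th$lambda * sdGA / sdy)
  if (spec@structural) {
    sdx <- sqrt(diag(th$phi))
    rows <- rbind(rows, data.frame(
      param = paste0(spec@latent, "~", spec@predictors),
      type = "path", est = th$gamma, std = th$gamma * sdx / sdGA))
  }
  rows <- rbind(rows, data.frame(
    param = paste0(spec@latent, "~~", spec@latent), type = "variance",
    est = th$psi, std = th$psi / th$varLatent))
  rows <- rbind(rows, data.frame(
    param = paste0(spec@indicators, "~~", spec@indicators),
    type = "residual",
    est = diag(th$theta), std = diag(th$theta) / sdy^2))
  if (nrow(spec@residualCov)) {
    ii <- match(spec@residualCov[, 1L], spec@indicators)
    jj <- match(spec@residualCov[, 2L], spec@indicators)
    rows <- rbind(rows, data.frame(
      param = paste0(spec@residualCov[, 1L], "~~",
                     spec@residualCov[, 2L]),
      type = "residual_cov",
      est = th$theta[cbind(ii, jj)],
      std = th$theta[cbind(ii, jj)] / (sdy[ii] * sdy[jj])))
  }
  rownames(rows) <- NULL
  rows
}

## ---- two-step procedure ---------------------------------------------

.thresholdReport <- function(ind) {
  data.frame(
    index = c("cfi", "tli", "rmsea", "srmr"),
    value = c(ind$cfi, ind$tli, ind$rmsea, ind$srmr),
    threshold = c(0.95, 0.95, 0.08, 0.10),
    rule = c(">=", ">=", "<=", "<="),
    pass = c(ind$cfi >= 0.95, ind$tli >= 0.95,
             ind$rmsea <= 0.08, ind$srmr <= 0.10))
}

#' Two-step MIMIC estimation
#'
#' Step 1 fits the measurement model alone (CFA) and evaluates it against
#' conventional thresholds (CFI and TLI at least 0.95, RMSEA at most 0.08,
#' SRMR at most 0.10). Step 2 fits the full structural model. Step 2 is
#' executed even when step 1 fails the thresholds (with a warning), so the
#' pipeline remains inspectable.
#'
#' @param spec the full [MimicSpec-class] (structural part on).
#' @param data,moments as in [fitMimic()].
#' @return list of class `"twoStepFit"` with elements `cfa` and
#'   `structural`, each holding `fit`, `indices` and a `report` data.frame
#'   of threshold checks.
#' @export
twoStepFit <- function(spec, data = NULL, moments = NULL) {
  if (!spec@structural)
    stop("'spec' must include the structural part", call. = FALSE)
  if (is.null(moments)) {
    vars <- c(spec@indicators, spec@predictors)
    moments <- sampleMoments(data, vars)
  }
  cfa <- fitMimic(cfaSpec(spec), moments = moments)
  cfaInd <- fitIndices(cfa)
  cfaRep <- .thresholdReport(cfaInd)
  if (!all(cfaRep$pass))
    warning("measurement model fails fit thresholds: ",
            paste(cfaRep$index[!cfaRep$pass], collapse = ", "),
            "; proceeding to the structural step anyway", call. = FALSE)
  full <- fitMimic(spec, moments = moments)
  fullInd <- fitIndices(full)
  structure(list(
    cfa = list(fit = cfa, indices = cfaInd, report = cfaRep),
    structural = list(fit = full, indices = fullInd,
                      report = .thresholdReport(fullInd))),
    class = "twoStepFit")
}

#' @export
print.twoStepFit <- function(x, ...) {
  cat("== Step 1: measurement model (CFA) ==\n")
  print(x$cfa$indices)
  cat("\n== Step 2: full MIMIC model ==\n")
  print(x$structural$indices)
  std <- standardizedSolution(x$structural$fit)
  cat("\nStandardized loadings:\n")
  print(std[std$type == "loading", c("param", "std")], row.names = FALSE)
  cat("\nStandardized paths:\n")
  print(std[std$type == "path", c("param", "std")], row.names = FALSE)
  invisible(x)
}
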
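## Synthetic cohorts drawn from a specified MIMIC generating model, in the
## standardized metric (unit-variance latent, indicators and predictors),
## plus the exact implied population covariance for zero-discrepancy tests.

## default generating values (standardized): loadings per indicator,
## structural paths, residual covariances for the four adjacent-slice pairs
.DEFAULT_LOADINGS <- c(dg = 0.79, a68 = 0.82, a78 = 0.85, a88 = 0.87,
                       a98 = 0.68, a108 = 0.72, c84 = 0.84, c94 = 0.81,
                       c104 = 0.69, c114 = 0.78, c124 = 0.64)
.DEFAULT_PATHS <- c(ses = -0.22, age = 0.57, sex = 0.40)
.DEFAULT_RESID_COV <- 0.10

## truncated normal moments and sampler (inverse-CDF)
.truncNormMoments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sd * (da - db) / Z
  v <- sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

.rTruncNorm <- function(n, mu, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm((lo - mu) / sd),
                    stats::pnorm((hi - mu) / sd))
  mu + sd * stats::qnorm(u)
}

#' Generating parameters of a synthetic MIMIC cohort
#'
#' Defaults emulate the study conditions: standardized loadings 0.64--0.87
#' over the 11 slice indicators, standardized paths (ses -0.22, age 0.57,
#' sex 0.40), SES categorical on 1--4 with probabilities
#' 25.8/34.8/22/17.4%, age normal(69, 12) truncated to \[33, 94\], sex
#' Bernoulli(0.28) for male = 1, and residual covariance 0.10 for each of
#' the four adjacent-slice pairs.
#'
#' @param loadings named length-11 numeric vector of standardized loadings.
#' @param paths named numeric vector of standardized structural paths
#'   (order defines the predictor order).
#' @param residCov residual covariance value(s) for the pairs in
#'   `residPairs` (recycled).
#' @param residPairs list of indicator-name pairs.
#' @param sesProbs probabilities of SES levels 1..length(sesProbs).
#' @param ageMean,ageSD,ageRange age distribution (normal, truncated).
#' @param pMale probability of male (sex = 1).
#' @return list of class `"CohortParams"`; construction fails if the
#'   implied covariance matrix is not positive definite, naming the
#'   offending block.
#' @export
cohortParams <- function(loadings = .DEFAULT_LOADINGS,
                         paths = .DEFAULT_PATHS,
                         residCov = .DEFAULT_RESID_COV,
                         residPairs = list(c("c94", "c104"),
                                           c("c104", "c114"),
                                           c("c114", "c124"),
                                           c("a68", "a78")),
                         sesProbs = c(0.258, 0.348, 0.22, 0.174),
                         ageMean = 69, ageSD = 12, ageRange = c(33, 94),
                         pMale = 0.28) {
  if (is.null(names(loadings)))
    names(loadings) <- .INDICATORS[seq_along(loadings)]
  if (is.null(names(paths))) names(paths) <- c("ses", "age", "sex")
  residCov <- rep_len(residCov, length(residPairs))
  psi <- 1 - sum(paths^2)        # predictors independent, unit variance
  if (psi <= 0)
    stop("paths imply non-positive latent disturbance variance (psi = ",
         round(psi, 4), ")", call. = FALSE)
  Theta <- diag(1 - loadings^2)
  dimnames(Theta) <- list(names(loadings), names(loadings))
  if (any(diag(Theta) <= 0))
    stop("loadings imply non-positive residual variances for: ",
         paste(names(loadings)[diag(Theta) <= 0], collapse = ", "),
         call. = FALSE)
  for (k in seq_along(residPairs)) {
    pr <- residPairs[[k]]
    Theta[pr[1], pr[2]] <- Theta[pr[2], pr[1]] <- residCov[k]
  }
  if (inherits(tryCatch(chol(Theta), error = function(e) e), "error"))
    stop("residual covariance block is not positive definite",
         call. = FALSE)
  params <- list(loadings = loadings, paths = paths, psi = psi,
                 Theta = Theta, residPairs = residPairs,
                 residCov = residCov, sesProbs = sesProbs / sum(sesProbs),
                 ageMean = ageMean, ageSD = ageSD, ageRange = ageRange,
                 pMale = pMale)
  ## full implied covariance must be PD too
  if (inherits(tryCatch(chol(populationMoments(params)$cov),
                        error = function(e) e), "error"))
    stop("implied population covariance is not positive definite",
         call. = FALSE)
  class(params) <- "CohortParams"
  params
}

## population mean/sd of the raw predictor scales
.predictorScales <- function(params) {
  lv <- seq_along(params$sesProbs)
  sesMean <- sum(lv * params$sesProbs)
  sesSD <- sqrt(sum((lv - sesMean)^2 * params$sesProbs))
  age <- .truncNormMoments(params$ageMean, params$ageSD,
                           params$ageRange[1], params$ageRange[2])
  sexMean <- params$pMale
  sexSD <- sqrt(params$pMale * (1 - params$pMale))
  data.frame(predictor = c("ses", "age", "sex"),
             mean = c(sesMean, age["mean"], sexMean),
             sd = c(sesSD, age["sd"], sexSD))
}

#' Exact population moments of the generating MIMIC model
#'
#' Implied covariance over the 11 indicators and the standardized
#' predictors (`ses_z`, `age_z`, `sex_z`): predictors independent with
#' unit variance, latent variance `paths'paths + psi = 1`, indicator block
#' `loadings loadings' + Theta`.
#'
#' @param params a [cohortParams()] object.
#' @param n nominal sample size attached to the moments (for fitting).
#' @return a [momentsFromCov()] moments list.
#' @export
populationMoments <- function(params = cohortParams(), n = 1000L) {
  lam <- params$loadings
  g <- params$paths
  q <- length(g)
  Syy <- tcrossprod(lam) + params$Theta
  Syx <- tcrossprod(lam, g)        # Phi = I in the standardized metric
  Sig <- rbind(cbind(Syy, Syx), cbind(t(Syx), diag(q)))
  nm <- c(names(lam), paste0(names(g), "_z"))
  dimnames(Sig) <- list(nm, nm)
  momentsFromCov(Sig, n)
}

#' Simulate a cohort from the generating MIMIC model
#'
#' Draws raw predictors (SES categorical, age truncated normal, sex
#' Bernoulli), standardizes them by their population moments, forms the
#' latent factor `GA = paths' x_z + zeta` and indicators
#' `y = loadings * GA + eps` with the specified residual covariance
#' structure, so the standardized generating values equal the configured
#' loadings and paths. Pure function of (params, seed).
#'
#' @param n number of subjects (>= 1).
#' @param params a [cohortParams()] object.
#' @param seed integer seed.
#' @return data.frame with `subject_id`, the 11 indicators, raw `age`,
#'   `sex`, `ses`, and population-standardized `ses_z`, `age_z`, `sex_z`.
#'   The generating parameters are attached as `attr(, "generating")`.
#' @examples
#' head(simulateCohort(5, seed = 1))
#' @export
simulateCohort <- function(n, params = cohortParams(), seed = NULL) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  sc <- .predictorScales(params)
  .withSeed(seed, {
    ses <- sample(seq_along(params$sesProbs), n, replace = TRUE,
                  prob = params$sesProbs)
    age <- .rTruncNorm(n, params$ageMean, params$ageSD,
                       params$ageRange[1], params$ageRange[2])
    sex <- stats::rbinom(n, 1L, params$pMale)
    X <- cbind(ses = (ses - sc$mean[1]) / sc$sd[1],
               age = (age - sc$mean[2]) / sc$sd[2],
               sex = (sex - sc$mean[3]) / sc$sd[3])
    ga <- drop(X %*% params$paths) +
      stats::rnorm(n, 0, sqrt(params$psi))
    chT <- chol(params$Theta)
    eps <- matrix(stats::rnorm(n * length(params$loadings)), n) %*% chT
    Y <- outer(ga, params$loadings) + eps
    colnames(Y) <- names(params$loadings)
    out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)), Y,
                      age = age, sex = sex, ses = ses,
                      ses_z = X[, "ses"], age_z = X[, "age"],
                      sex_z = X[, "sex"], stringsAsFactors = FALSE)
    attr(out, "generating") <- params
    out
  })
}

#' Generating values mapped onto the fitted parameterization
#'
#' The simulator parameterizes in the standardized metric; a fit with the
#' first loading fixed to 1 estimates the model in the scale of the first
#' indicator's latent projection. This helper maps the generating values
#' onto the free-parameter vector of a given specification, for parameter
#' recovery and zero-discrepancy checks.
#'
#' @param spec a [MimicSpec-class] whose indicator order matches the
#'   generating loadings.
#' @param params a [cohortParams()] object.
#' @return named numeric vector aligned with `coef()` of the corresponding
#'   fit.
#' @export
generatingFreeParams <- function(spec, params = cohortParams()) {
  lam <- params$loadings[spec@indicators]
  g <- if (spec@structural) unname(params$paths) else numeric(0)
  psi <- params$psi
  Theta <- params$Theta[spec@indicators, spec@indicators]
  if (!spec@structural) {
    ## in a CFA the latent variance is the total variance (= 1 here)
    psi <- psi + sum(params$paths^2)
  }
  if (spec@identification == "fix_first_loading") {
    s <- lam[1L]
    lam <- lam / s
    g <- g * s
    psi <- psi * s^2
  }
  .freeFromTheta(spec, lam, g, psi, Theta)
}
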
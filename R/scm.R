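# Subtype classification model (SCM). A 3-component bivariate Gaussian
# mixture over scaled (ER, HER2) module scores separates basal, HER2 and
# luminal samples; components are labelled by their means (the component with
# the highest ER mean is luminal; of the remaining two the one with the
# higher HER2 mean is HER2; the last is basal). Luminal samples are then
# split into luminal A (low proliferation) and luminal B (high proliferation)
# via a univariate 2-component mixture over the proliferation score.
# Mixtures are fitted with mclust (full covariance, deterministic model-based
# agglomerative initialization); posteriors at predict time are computed
# in-package from the stored parameters.

.covConditionBound <- 1e8

.checkMclustFit <- function(fit, what) {
  if (is.null(fit))
    stop("EM failure while fitting the ", what, " mixture")
  fit
}

.fitUnivariateMixture <- function(x, what = "univariate",
                                  modelNames = c("V", "E")) {
  fit <- NULL
  for (mn in modelNames) {
    fit <- suppressWarnings(mclust::Mclust(x, G = 2L, modelNames = mn,
                                           verbose = FALSE))
    if (!is.null(fit)) break
  }
  fit <- .checkMclustFit(fit, what)
  mu <- as.numeric(fit$parameters$mean)
  sig2 <- fit$parameters$variance$sigmasq
  if (length(sig2) == 1L) sig2 <- rep(sig2, 2L)
  pro <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  list(pi = pro[ord[1L]], muLow = mu[ord[1L]], muHigh = mu[ord[2L]],
       sdLow = sqrt(sig2[ord[1L]]), sdHigh = sqrt(sig2[ord[2L]]))
}

#' Fit a subtype classification model
#'
#' @param scores a scaled [ModuleScores-class] with at least the ER, HER2 and
#'   PROLIF columns and at least `minSamples` samples.
#' @param seed integer seed driving the k-means restart initializations.
#' @param nRestarts number of seeded k-means initializations tried in
#'   addition to the deterministic model-based agglomerative start; the fit
#'   with the best log-likelihood wins (default 10).
#' @param minSamples minimum number of samples (default 30).
#' @return An [SCMModel-class].
#' @export
fitSCM <- function(scores, seed = NULL, nRestarts = 10L, minSamples = 30L) {
  stopifnot(is(scores, "ModuleScores"))
  if (!isScaled(scores))
    stop("SCM fitting requires robustly scaled module scores")
  sc <- moduleScores(scores)
  need <- c("ER", "HER2", "PROLIF")
  if (!all(need %in% colnames(sc)))
    stop("missing module column(s): ",
         paste(setdiff(need, colnames(sc)), collapse = ", "))
  if (nrow(sc) < minSamples)
    stop("at least ", minSamples, " samples required to fit an SCM")
  fit <- .fitBivariateMixture(sc[, c("ER", "HER2")], seed = seed,
                              nRestarts = nRestarts)
  means <- fit$means
  rownames(means) <- c("ER", "HER2")
  covs <- fit$covariances
  for (k in seq_len(3L)) {
    ev <- eigen(covs[[k]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / min(ev) > .covConditionBound)
      stop(sprintf(
        "degenerate mixture component %d (covariance eigenvalues %.3g / %.3g)",
        k, max(ev), min(ev)))
  }
  # component labelling: highest ER mean is luminal; of the remaining two the
  # higher HER2 mean is HER2; the last is basal
  compMap <- character(3L)
  lumComp <- which.max(means["ER", ])
  compMap[lumComp] <- "LUMINAL"
  rest <- setdiff(seq_len(3L), lumComp)
  her2Comp <- rest[which.max(means["HER2", rest])]
  compMap[her2Comp] <- "HER2"
  compMap[setdiff(rest, her2Comp)] <- "BASAL"

  luminal <- apply(fit$z, 1L, which.max) == lumComp
  if (sum(luminal) < 10L)
    stop("fewer than 10 luminal samples; cannot fit the proliferation split")
  prolifSplit <- .fitUnivariateMixture(sc[luminal, "PROLIF"],
                                       what = "proliferation")
  new("SCMModel", mglId = scores@mglId, weights = as.numeric(fit$weights),
      means = means, covariances = covs, compMap = compMap,
      prolifSplit = prolifSplit, trainingSetId = datasetId(scores))
}

# Best-of-restarts 3-component full-covariance bivariate mixture: the
# deterministic agglomerative initialization of mclust plus seeded k-means
# starts, ranked by log-likelihood. Guards against the occasional poor local
# optimum of a single EM run.
.fitBivariateMixture <- function(x, seed = NULL, nRestarts = 10L) {
  x <- as.matrix(x)
  candidates <- list()
  hcFit <- suppressWarnings(mclust::Mclust(x, G = 3L, modelNames = "VVV",
                                           verbose = FALSE))
  if (!is.null(hcFit))
    candidates[[1L]] <- list(par = hcFit$parameters, z = hcFit$z,
                             loglik = hcFit$loglik)
  if (nRestarts > 0L) {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(nRestarts)) {
      km <- tryCatch(stats::kmeans(x, centers = 3L, nstart = 1L),
                     error = function(e) NULL)
      if (is.null(km) || length(unique(km$cluster)) < 3L) next
      z0 <- mclust::unmap(km$cluster, groups = 1:3)
      emFit <- tryCatch(
        suppressWarnings(mclust::meVVV(data = x, z = z0)),
        error = function(e) NULL)
      if (!is.null(emFit) && !is.null(emFit$parameters) &&
          is.finite(emFit$loglik))
        candidates[[length(candidates) + 1L]] <-
          list(par = emFit$parameters, z = emFit$z, loglik = emFit$loglik)
    }
  }
  if (length(candidates) == 0L)
    stop("EM failure while fitting the ER/HER2 mixture")
  best <- candidates[[which.max(vapply(candidates, `[[`, 0, "loglik"))]]
  covs <- lapply(seq_len(3L), function(k) best$par$variance$sigma[, , k])
  list(weights = as.numeric(best$par$pro), means = best$par$mean,
       covariances = covs, z = best$z, loglik = best$loglik)
}

# log density of a bivariate Gaussian at the rows of x
.logdmvnorm2 <- function(x, mu, sigma) {
  ch <- chol(sigma)
  xc <- sweep(x, 2L, mu)
  z <- xc %*% chol2inv(ch)  # n x 2, equals xc Sigma^-1
  quad <- rowSums(z * xc)
  -log(2 * pi) - sum(log(diag(ch))) - quad / 2
}

#' Component posterior probabilities under an SCM
#'
#' @param model an [SCMModel-class].
#' @param x numeric matrix with columns `ER`, `HER2`.
#' @return Matrix of posterior probabilities, columns named by the subtype
#'   group of each component (`BASAL`, `HER2`, `LUMINAL`), rows summing to 1.
#' @export
scmPosterior <- function(model, x) {
  x <- as.matrix(x[, c("ER", "HER2"), drop = FALSE])
  lp <- vapply(seq_len(3L), function(k)
    log(model@weights[k]) + .logdmvnorm2(x, model@means[, k],
                                         model@covariances[[k]]),
    numeric(nrow(x)))
  lp <- matrix(lp, nrow = nrow(x))
  mx <- apply(lp, 1L, max)
  post <- exp(lp - mx)
  post <- post / rowSums(post)
  colnames(post) <- model@compMap
  rownames(post) <- rownames(x)
  # canonical column order (BASAL, HER2, LUMINAL) for stable tie-breaking
  post[, order(match(colnames(post), c("BASAL", "HER2", "LUMINAL"))),
       drop = FALSE]
}

#' Predict subtypes with an SCM
#'
#' Per sample the posterior over the three mixture components is computed;
#' the maximum-posterior component decides between basal, HER2 and luminal
#' (exact ties broken by canonical order). Luminal samples are then assigned
#' luminal A when the posterior of the low-proliferation component is at
#' least that of the high component (`splitMode = "mixture"`, the default),
#' or by a fixed proliferation threshold (`splitMode = "threshold"`).
#'
#' @param model an [SCMModel-class].
#' @param scores a scaled [ModuleScores-class].
#' @param splitMode luminal A/B split rule: `"mixture"` or `"threshold"`.
#' @param threshold proliferation cutoff used when `splitMode = "threshold"`.
#' @return A [SubtypeAssignment-class]; the 3-component posterior matrix is
#'   attached as attribute `"posteriors"` and the low-proliferation posterior
#'   of every sample as attribute `"prolif_posterior_low"`.
#' @export
predictSCM <- function(model, scores, splitMode = c("mixture", "threshold"),
                       threshold = 0) {
  splitMode <- match.arg(splitMode)
  stopifnot(is(model, "SCMModel"), is(scores, "ModuleScores"))
  sc <- moduleScores(scores)
  need <- c("ER", "HER2", "PROLIF")
  if (!all(need %in% colnames(sc)))
    stop("missing module column(s): ",
         paste(setdiff(need, colnames(sc)), collapse = ", "))
  if (anyNA(sc[, need]))
    stop("missing module scores")
  post <- scmPosterior(model, sc)
  group <- colnames(post)[apply(post, 1L, which.max)]

  ps <- model@prolifSplit
  ll <- log(ps$pi) + dnorm(sc[, "PROLIF"], ps$muLow, ps$sdLow, log = TRUE)
  lh <- log(1 - ps$pi) + dnorm(sc[, "PROLIF"], ps$muHigh, ps$sdHigh,
                               log = TRUE)
  pLow <- 1 / (1 + exp(lh - ll))
  lum <- group == "LUMINAL"
  label <- group
  if (identical(splitMode, "mixture")) {
    label[lum] <- ifelse(pLow[lum] >= 0.5, "LUMA", "LUMB")
  } else {
    label[lum] <- ifelse(sc[lum, "PROLIF"] > threshold, "LUMB", "LUMA")
  }
  out <- SubtypeAssignment(rownames(sc), label,
                           predictorId = paste0("SCM.", model@mglId, ".",
                                                model@trainingSetId))
  attr(out, "posteriors") <- post
  attr(out, "prolif_posterior_low") <- stats::setNames(pLow, rownames(sc))
  out
}
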
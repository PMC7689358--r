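#' Fit GBLUP by spectral REML
#'
#' Fits the mixed model y = 1 mu + g + e with g ~ N(0, sigma_g^2 G) and
#' e ~ N(0, sigma_e^2 I) on the training individuals. Variance components
#' are estimated by REML: the training block of G is rotated into the
#' eigenbasis of the space orthogonal to the intercept, which reduces the
#' restricted likelihood to a one-dimensional function of
#' lambda = sigma_e^2 / sigma_g^2, maximized by golden-section/parabolic
#' search on log(lambda) in (-10, 10). Genetic values for *all*
#' individuals (trained and untrained) are then predicted through the
#' cross block of G:
#' \deqn{\hat g = G[, train] (G_{train} + \lambda I)^{-1} (y - \hat\mu).}
#' Test phenotypes are never read.
#'
#' @param grm a [vanraden_grm()] covering all individuals.
#' @param y_train numeric phenotypes of the training individuals.
#' @param train_ids integer indices (rows of the GRM) of the training
#'   individuals, in the same order as `y_train`.
#' @param lambda optional fixed variance ratio sigma_e^2 / sigma_g^2;
#'   when supplied REML maximization is skipped (useful for fitting at a
#'   known heritability, lambda = (1 - h2) / h2, or for studying the
#'   full-shrinkage limit lambda -> Inf).
#' @return Object of class `gblup_fit`: `mu`, `lambda`,
#'   `variance_components` (named sigma_g2, sigma_e2), `h2` (REML
#'   heritability estimate), `blup` (n-vector of predicted genetic values
#'   for every individual), `train_ids`, `loglik`.
#' @examples
#' panel <- simulate_genotype_panel(200, 300, 2, seed = 1)
#' ph <- simulate_trait(panel, 50, h2 = 0.5, seed = 2)
#' G <- vanraden_grm(panel)
#' fit <- gblup_fit(G, ph$phenotypes[1:150], 1:150)
#' fit$h2
#' @export
gblup_fit <- function(grm, y_train, train_ids, lambda = NULL) {
  stopifnot(inherits(grm, "grm"))
  y <- as.numeric(y_train)
  train_ids <- as.integer(train_ids)
  n_all <- nrow(grm$matrix)
  nt <- length(train_ids)
  if (nt < 3L) stop("at least 3 training individuals are required")
  if (length(y) != nt) stop("y_train and train_ids lengths differ")
  if (!all(is.finite(y))) stop("non-finite phenotypes")
  if (any(train_ids < 1L | train_ids > n_all)) stop("train_ids out of range")

  K <- grm$matrix[train_ids, train_ids]
  reml <- reml_single_kernel(K, y, lambda_fixed = lambda)

  mu <- reml$mu
  lambda <- reml$lambda
  blup <- if (is.infinite(lambda) || reml$sigma_g2 == 0) {
    rep(0, n_all)
  } else {
    Hinv_r <- solve(K + diag(lambda, nt), y - mu)
    as.numeric(grm$matrix[, train_ids] %*% Hinv_r)
  }
  structure(list(
    mu = mu, lambda = lambda,
    variance_components = c(sigma_g2 = reml$sigma_g2, sigma_e2 = reml$sigma_e2),
    h2 = reml$sigma_g2 / (reml$sigma_g2 + reml$sigma_e2),
    blup = blup, train_ids = train_ids, loglik = reml$loglik
  ), class = "gblup_fit")
}

# one-kernel REML via eigendecomposition on the intercept-orthogonal space
#' @noRd
reml_single_kernel <- function(K, y, lambda_fixed = NULL) {
  nt <- length(y)
  Q <- qr.Q(qr(cbind(rep(1, nt), diag(nt))))[, 2:nt, drop = FALSE]
  A <- crossprod(Q, K %*% Q)
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  theta <- pmax(ev$values, 0)
  eta <- as.numeric(crossprod(ev$vectors, crossprod(Q, y)))

  neg_restricted <- function(loglambda) {
    lam <- exp(loglambda)
    d <- theta + lam
    s2 <- sum(eta^2 / d) / (nt - 1)
    0.5 * ((nt - 1) * log(s2) + sum(log(d)))
  }
  if (is.null(lambda_fixed)) {
    opt <- optimize(neg_restricted, interval = c(-10, 10), tol = 1e-10)
    lambda <- exp(opt$minimum)
    obj <- opt$objective
  } else {
    stopifnot(lambda_fixed > 0)
    lambda <- lambda_fixed
    obj <- neg_restricted(log(lambda))
  }
  d <- theta + lambda
  sigma_g2 <- sum(eta^2 / d) / (nt - 1)
  sigma_e2 <- lambda * sigma_g2
  # GLS intercept under the fitted covariance
  Hinv1 <- solve(K + diag(lambda, nt), rep(1, nt))
  mu <- sum(Hinv1 * y) / sum(Hinv1)
  list(mu = mu, lambda = lambda, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
       loglik = -obj)
}

#' Predictions from a fitted linear model
#'
#' Returns phenotype-scale predictions mu + g_hat for the requested
#' individuals. Only the fit object is consulted; no phenotype of the
#' requested individuals is read.
#'
#' @param fit a `gblup_fit`, `egblup_fit` or `bayesa_fit`.
#' @param test_ids integer indices of the individuals to predict (may
#'   include training individuals, returning their in-sample BLUPs).
#' @return numeric vector of predictions, one per id; empty input gives
#'   an empty vector.
#' @export
predict_lm <- function(fit, test_ids) UseMethod("predict_lm")

#' @export
predict_lm.gblup_fit <- function(fit, test_ids) {
  test_ids <- as.integer(test_ids)
  if (length(test_ids) == 0L) return(numeric(0))
  if (any(test_ids < 1L | test_ids > length(fit$blup))) stop("unknown ids")
  fit$mu + fit$blup[test_ids]
}

#' @export
predict_lm.egblup_fit <- function(fit, test_ids) {
  predict_lm.gblup_fit(fit, test_ids)
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<gblup_fit> mu = %.4f, lambda = %.4g, h2 = %.3f (n_train = %d)\n",
              x$mu, x$lambda, x$h2, length(x$train_ids)))
  invisible(x)
}
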
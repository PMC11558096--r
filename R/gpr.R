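# Gaussian process regression calibration: RGB features -> concentration.
#
# RBF (squared-exponential) kernel on internally standardised features,
# targets on the raw ng/mL scale centred at their mean (which acts as the
# prior mean, so far-field predictions revert to it). Hyperparameters by
# multi-start L-BFGS-B maximisation of the log marginal likelihood.

# Squared Euclidean distance matrix between rows of A and B.
sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Fit a Gaussian process regression calibration model
#'
#' Kernel \eqn{k(u, v) = \sigma_f^2 \exp(-\|u - v\|^2 / (2\ell^2))} plus a
#' noise variance \eqn{\sigma_n^2} on the diagonal (with a fixed jitter for
#' numerical stability). Features are standardised to zero mean / unit
#' variance internally; the transform is stored in the model. When
#' `optimize = TRUE` the hyperparameters maximise the log marginal
#' likelihood
#' \deqn{\log p(y) = -\tfrac12 y^\top (K + \sigma_n^2 I)^{-1} y
#'   - \tfrac12 \log|K + \sigma_n^2 I| - \tfrac{n}{2}\log 2\pi}
#' over `restarts` deterministic-seeded starts of L-BFGS-B in log-parameter
#' space.
#'
#' @param train_rgb Numeric matrix (n x p) of features.
#' @param train_conc Numeric targets (ng/mL), length n.
#' @param optimize Optimise hyperparameters? Requires n >= 2.
#' @param restarts Number of optimiser starts (the first is a fixed
#'   data-scaled start; the rest are randomised from `seed`).
#' @param seed Integer seed for the randomised restarts.
#' @param kernel Optional fixed hyperparameters, a list with
#'   `signal_variance`, `length_scale`, `noise_variance`; used as-is when
#'   `optimize = FALSE`.
#' @param jitter Diagonal jitter added to the noise variance.
#' @return An object of class `uelfa_gpr` with the kernel, the Cholesky
#'   factor of \eqn{K + \sigma_n^2 I} and the weight vector
#'   \eqn{\alpha = (K + \sigma_n^2 I)^{-1} (y - \bar y)}.
#' @export
gpr_fit <- function(train_rgb, train_conc, optimize = TRUE, restarts = 3,
                    seed = NULL, kernel = NULL, jitter = 1e-10) {
  X <- as.matrix(train_rgb)
  y <- as.numeric(train_conc)
  n <- nrow(X)
  assert_that(n >= 1 && length(y) == n, "features and targets must align")
  if (optimize) assert_that(n >= 2, "optimisation requires n >= 2")

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  ym <- mean(y)
  yc <- y - ym
  D2 <- sqdist(Xs, Xs)

  nll <- function(theta) {
    sf2 <- exp(theta[1]); ell <- exp(theta[2]); sn2 <- exp(theta[3])
    Kmat <- sf2 * exp(-D2 / (2 * ell^2))
    diag(Kmat) <- diag(Kmat) + sn2 + jitter
    U <- tryCatch(chol(Kmat), error = function(e) NULL)
    if (is.null(U)) return(1e10)
    alpha <- backsolve(U, backsolve(U, yc, transpose = TRUE))
    0.5 * sum(yc * alpha) + sum(log(diag(U))) + n / 2 * log(2 * pi)
  }

  if (!optimize) {
    if (is.null(kernel)) {
      vy <- max(stats::var(y), 1e-8)
      if (!is.finite(vy)) vy <- 1
      kernel <- list(signal_variance = vy, length_scale = 1,
                     noise_variance = 0.01 * vy)
    }
    theta <- log(c(kernel$signal_variance, kernel$length_scale,
                   kernel$noise_variance))
  } else {
    vy <- max(stats::var(y), 1e-8)
    lower <- c(-15, -9, -26)
    upper <- c(12, 6, 6)
    start0 <- c(log(vy), 0, log(vy) - 4)
    starts <- list(start0)
    if (restarts > 1) {
      extra <- with_seed(seed, {
        lapply(seq_len(restarts - 1), function(i) {
          c(log(vy) + stats::runif(1, -2, 2),
            stats::runif(1, -6, 2),
            stats::runif(1, -20, log(vy)))
        })
      })
      starts <- c(starts, extra)
    }
    fits <- lapply(starts, function(s) {
      tryCatch(
        stats::optim(s, nll, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 200)),
        error = function(e) list(value = Inf, par = s)
      )
    })
    best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
    if (!is.finite(best$value)) stop("GPR optimisation failed", call. = FALSE)
    theta <- best$par
  }

  sf2 <- exp(theta[1]); ell <- exp(theta[2]); sn2 <- exp(theta[3])
  Kmat <- sf2 * exp(-D2 / (2 * ell^2))
  diag(Kmat) <- diag(Kmat) + sn2 + jitter
  U <- tryCatch(chol(Kmat), error = function(e) {
    stop("kernel matrix singular even after jitter", call. = FALSE)
  })
  alpha <- backsolve(U, backsolve(U, yc, transpose = TRUE))
  lml <- -(0.5 * sum(yc * alpha) + sum(log(diag(U))) + n / 2 * log(2 * pi))

  structure(
    list(train_rgb = X, train_conc = y, Xs = Xs, center = ctr, scale = scl,
         y_mean = ym,
         kernel = list(signal_variance = sf2, length_scale = ell,
                       noise_variance = sn2),
         jitter = jitter, chol_upper = U, alpha = alpha,
         log_marginal_likelihood = lml, optimized = optimize),
    class = "uelfa_gpr"
  )
}

#' Posterior prediction from a fitted GPR model
#'
#' Posterior mean \eqn{\bar y + k_*^\top \alpha} and latent variance
#' \eqn{k(q,q) - k_*^\top (K + \sigma_n^2 I)^{-1} k_*}, clipped at zero (a
#' warning is raised if the raw value falls below -1e-9, which would indicate
#' a numerical problem rather than rounding).
#'
#' @param model A fitted `uelfa_gpr`.
#' @param query_rgb Query features, vector (single query) or matrix.
#' @return A list with numeric vectors `mean` (ng/mL) and `variance`.
#' @export
gpr_predict <- function(model, query_rgb) {
  assert_that(inherits(model, "uelfa_gpr") && !is.null(model$chol_upper),
              "`model` must be a fitted uelfa_gpr")
  if (is.null(dim(query_rgb))) query_rgb <- matrix(query_rgb, nrow = 1)
  Q <- scale(as.matrix(query_rgb), center = model$center, scale = model$scale)
  k <- model$kernel
  Kstar <- k$signal_variance *
    exp(-sqdist(Q, model$Xs) / (2 * k$length_scale^2))   # m x n
  mu <- model$y_mean + as.numeric(Kstar %*% model$alpha)
  V <- backsolve(model$chol_upper, t(Kstar), transpose = TRUE)  # n x m
  varq <- k$signal_variance - colSums(V^2)
  if (any(varq < -1e-9)) {
    warning("posterior variance below -1e-9 clipped to zero; ",
            "kernel conditioning is suspect")
  }
  list(mean = mu, variance = pmax(varq, 0))
}

#' @export
print.uelfa_gpr <- function(x, ...) {
  k <- x$kernel
  cat("GPR calibration: n =", length(x$train_conc), "\n")
  cat(sprintf("  kernel: sigma_f^2 = %.4g, length_scale = %.4g, sigma_n^2 = %.4g\n",
              k$signal_variance, k$length_scale, k$noise_variance))
  cat(sprintf("  log marginal likelihood: %.4f (%s)\n",
              x$log_marginal_likelihood,
              if (x$optimized) "optimised" else "fixed"))
  invisible(x)
}
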
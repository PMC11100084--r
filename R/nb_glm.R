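#' Fit the null negative-binomial GLM
#'
#' Regresses a response count vector `Y` on the technical covariates `Z`
#' only (no treatment term) with a log link:
#' `Y_i ~ NB_theta(mu_i), log(mu_i) = beta' Z_i`.
#' Fitting is by iteratively reweighted least squares; when the family is
#' `"nb"` the size parameter theta is re-estimated between IRLS sweeps by
#' Newton's method on log(theta) (see [estimate_theta()]). The fit exposes
#' exactly the quantities the score test consumes: fitted means `mu_hat`,
#' weights `w_i = mu_i / (1 + mu_i/theta)`, and working residuals
#' `Y_i/mu_i - 1`.
#'
#' @param Y nonnegative integer response vector (one response, all cells).
#' @param Z full-column-rank covariate matrix from
#'   [build_covariate_matrix()].
#' @param family `"nb"` (theta estimated), `"poisson"`, or a single
#'   positive number interpreted as a fixed NB theta (`Inf` = Poisson).
#' @param max_iter,tol IRLS iteration cap and relative-deviance tolerance.
#' @return object of class `null_fit`: `beta_hat`, `theta_hat` (`Inf` for
#'   Poisson), `mu_hat`, `w`, `working_resid`, `family_tag`, `converged`,
#'   `loglik`, and `theta_flag` (`"upper"` if theta hit its upper clamp,
#'   i.e. no detectable overdispersion).
#' @export
fit_null_glm <- function(Y, Z, family = "nb", max_iter = 50, tol = 1e-8) {
  if (any(!is.finite(Z))) stop("input error: non-finite covariate")
  if (any(Y < 0) || any(Y != floor(Y)))
    stop("input error: Y must be nonnegative integers")
  if (all(Y == 0)) stop("degenerate-response error: all-zero Y")
  n <- length(Y)
  stopifnot(nrow(Z) == n)

  theta_fixed <- NULL
  if (is.numeric(family)) {
    stopifnot(length(family) == 1, family > 0)
    theta_fixed <- family
    family <- if (is.infinite(family)) "poisson" else "nb_fixed"
  }

  irls <- function(theta, beta0 = NULL) {
    # log link IRLS for fixed theta (Inf = Poisson)
    beta <- beta0
    if (is.null(beta)) {
      eta <- log(pmax(Y, 0.125))
      beta <- qr.solve(Z, eta)
    }
    mu <- as.vector(exp(Z %*% beta))
    dev_old <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- if (is.infinite(theta)) mu else mu / (1 + mu / theta)
      w <- pmax(w, 1e-10)
      zwork <- log(mu) + (Y - mu) / mu
      fit <- lm.wfit(Z, zwork, w)
      beta <- fit$coefficients
      mu <- pmax(as.vector(exp(Z %*% beta)), 1e-10)
      dev <- -2 * nb_loglik(Y, mu, theta)
      if (is.finite(dev_old) &&
          abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
        converged <- TRUE
        break
      }
      dev_old <- dev
    }
    list(beta = beta, mu = mu, converged = converged)
  }

  if (family == "poisson") {
    res <- irls(Inf)
    theta <- Inf
    conv <- res$converged
  } else if (family == "nb_fixed") {
    res <- irls(theta_fixed)
    theta <- theta_fixed
    conv <- res$converged
  } else if (family == "nb") {
    # alternate mean fit and dispersion update, starting from Poisson means
    res <- irls(Inf)
    theta <- estimate_theta(Y, res$mu)
    conv <- FALSE
    for (outer in 1:25) {
      res <- irls(theta, beta0 = res$beta)
      theta_new <- estimate_theta(Y, res$mu)
      done <- abs(log(min(theta_new, 1e6)) - log(min(theta, 1e6))) < 1e-6
      theta <- theta_new
      if (done && res$converged) {
        conv <- TRUE
        break
      }
    }
  } else stop("unknown family: ", family)

  if (!conv && family != "poisson") {
    # robust fallback: Poisson fit (always well behaved for log link)
    sp_log("NB fit did not converge; falling back to Poisson")
    res <- irls(Inf)
    theta <- Inf
    family <- "poisson"
    conv <- res$converged
  }

  mu <- res$mu
  theta_flag <- attr(theta, "flag") %||% "interior"
  if (is.finite(theta) && theta >= 1000) theta_flag <- "upper"
  w <- if (is.infinite(theta)) mu else mu / (1 + mu / theta)
  structure(list(
    beta_hat = res$beta,
    theta_hat = as.numeric(theta),
    mu_hat = mu,
    w = w,
    working_resid = Y / mu - 1,
    family_tag = if (is.infinite(theta)) "poisson" else "nb",
    converged = conv,
    theta_flag = theta_flag,
    loglik = nb_loglik(Y, mu, theta),
    Y = Y
  ), class = "null_fit")
}

# NB (or Poisson for theta = Inf) log-likelihood at given means.
nb_loglik <- function(Y, mu, theta) {
  if (is.infinite(theta)) {
    sum(dpois(Y, mu, log = TRUE))
  } else {
    sum(dnbinom(Y, size = theta, mu = mu, log = TRUE))
  }
}

#' Maximum-likelihood NB size parameter given fitted means
#'
#' Newton iteration on `log(theta)` for the profile likelihood of the NB
#' size parameter with the mean vector held fixed. The estimate is
#' clamped to `[theta_min, theta_max]`; data with no detectable
#' overdispersion (the MLE diverges) return `theta_max` with attribute
#' `flag = "upper"`, which callers treat as effectively Poisson.
#'
#' @param Y count vector.
#' @param mu_hat fitted mean vector from a converged mean-model fit.
#' @param theta_min,theta_max clamping bounds.
#' @return positive scalar, with attribute `flag` in
#'   `c("interior", "lower", "upper")`.
#' @export
estimate_theta <- function(Y, mu_hat, theta_min = 0.01, theta_max = 1000) {
  n <- length(Y)
  score_fn <- function(theta) {
    sum(digamma(Y + theta) - digamma(theta) + log(theta) + 1 -
          log(theta + mu_hat) - (Y + theta) / (theta + mu_hat))
  }
  # moment start: solve sum((y-mu)^2) = sum(mu + mu^2/theta)
  excess <- sum((Y - mu_hat)^2 - mu_hat)
  theta <- if (excess > 0) sum(mu_hat^2) / excess else theta_max
  theta <- min(max(theta, theta_min), theta_max)
  flag <- "interior"
  lt <- log(theta)
  for (it in 1:50) {
    theta <- exp(lt)
    s <- score_fn(theta)
    info <- sum(trigamma(Y + theta) - trigamma(theta) + 1 / theta -
                  2 / (theta + mu_hat) +
                  (Y + theta) / (theta + mu_hat)^2)
    # d/dlt loglik = theta * s; d2/dlt2 = theta*s + theta^2*info
    g <- theta * s
    h <- theta * s + theta^2 * info
    if (!is.finite(g) || !is.finite(h) || h >= 0) {
      step <- sign(g) * 0.5  # fall back to fixed step uphill
    } else {
      step <- -g / h
    }
    step <- max(min(step, 2), -2)
    lt_new <- lt + step
    lt_new <- min(max(lt_new, log(theta_min)), log(theta_max))
    if (abs(lt_new - lt) < 1e-10) {
      lt <- lt_new
      break
    }
    lt <- lt_new
  }
  theta <- exp(lt)
  if (theta >= theta_max * (1 - 1e-8)) {
    theta <- theta_max
    flag <- "upper"
  } else if (theta <= theta_min * (1 + 1e-8)) {
    theta <- theta_min
    flag <- "lower"
  }
  attr(theta, "flag") <- flag
  theta
}

#' @export
print.null_fit <- function(x, ...) {
  cat("null_fit (", x$family_tag, "): n =", length(x$mu_hat),
      ", theta =", signif(x$theta_hat, 4),
      ", converged =", x$converged, "\n")
  invisible(x)
}
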
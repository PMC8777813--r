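#' Four-parameter logistic (4PL) curve
#'
#' \deqn{Y(x) = d + \frac{a - d}{1 + (x/c)^b}} with upper/lower plateaus
#' `a` (low-x) and `d` (high-x), Hill slope `b`, and inflection point `c`.
#' In cavitation-threshold analysis `x` is the mechanical index and `c` is
#' taken as the cavitation threshold.
#'
#' @param x abscissa (MI), vectorized.
#' @param a,d plateaus; `a` is the value as `x -> 0`, `d` as `x -> Inf`.
#' @param b Hill slope.
#' @param c inflection point (> 0).
#' @return Numeric vector of responses.
#' @export
fourpl <- function(x, a, d, b, c) {
  d + (a - d) / (1 + (x / c)^b)
}

# numerical Jacobian of a residual function (central differences)
.num_jacobian <- function(fn, theta, eps = 1e-6) {
  r0 <- fn(theta)
  J <- matrix(0, length(r0), length(theta))
  for (k in seq_along(theta)) {
    h <- eps * max(1, abs(theta[k]))
    up <- theta; up[k] <- up[k] + h
    dn <- theta; dn[k] <- dn[k] - h
    J[, k] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

#' Fit 4PL cavitation-threshold curves
#'
#' Nonlinear least-squares fit of [fourpl()] to one or more MI-response
#' datasets (e.g., subharmonic magnitude or spectral integral vs MI, one
#' dataset per agent).  With `share_plateaus = TRUE` (the default) the
#' plateaus `a` and `d` are common to all datasets and estimated jointly,
#' while the Hill slope `b` and inflection `c` remain per-dataset; the
#' alternative reading (fully independent fits) is available with
#' `share_plateaus = FALSE`.  The inflection MI `c` is the cavitation
#' threshold; its 95% confidence interval comes from the parameter
#' covariance \eqn{\hat\sigma^2 (J^\top J)^{-1}} of the (joint) fit.
#'
#' @param responses a data.frame with columns `mi` and `response`, or a
#'   named list of such data.frames (one per agent).  Replicate rows per MI
#'   are allowed; at least 4 distinct MI levels spanning the transition are
#'   required per dataset.
#' @param share_plateaus logical; fit common `a`, `d` across datasets.
#' @param conf confidence level for the `c` interval.
#' @return A named list of `logistic_fit_4pl` objects (a single unnamed
#'   dataset yields a one-element list named `"1"`), each with fields `a`,
#'   `d`, `b`, `c`, `c_se`, `c_ci` (length 2), `threshold` (= `c`),
#'   `flagged` (TRUE when `c` falls outside the fitted MI range),
#'   `residual_ss`, `df`, `n`, `mi_range`, `shared_plateaus`.
#' @examples
#' mi <- seq(0.02, 1.2, length.out = 30)
#' y <- fourpl(mi, a = 0, d = -30, b = 8, c = 0.3)
#' fit_4pl(data.frame(mi = mi, response = y))[[1]]$c   # 0.3
#' @export
fit_4pl <- function(responses, share_plateaus = TRUE, conf = 0.95) {
  if (is.data.frame(responses)) responses <- list(`1` = responses)
  stopifnot(is.list(responses), length(responses) >= 1L)
  if (is.null(names(responses))) names(responses) <- seq_along(responses)
  for (nm in names(responses)) {
    df <- responses[[nm]]
    stopifnot(all(c("mi", "response") %in% names(df)))
    if (length(unique(df$mi)) < 4L) {
      stop(sprintf("dataset '%s' has fewer than 4 distinct MI levels", nm))
    }
  }
  if (!share_plateaus && length(responses) > 1L) {
    out <- lapply(responses, fit_4pl, share_plateaus = FALSE, conf = conf)
    return(lapply(out, `[[`, 1L))
  }

  K <- length(responses)
  # starting values: plateaus from the response extremes, c from the
  # midpoint crossing, b from the sign of the trend
  starts <- lapply(responses, function(df) {
    agg <- tapply(df$response, df$mi, mean)
    x <- as.numeric(names(agg))
    y <- as.numeric(agg)
    a0 <- y[which.min(x)]
    d0 <- y[which.max(x)]
    mid <- (a0 + d0) / 2
    c0 <- x[which.min(abs(y - mid))]
    list(a = a0, d = d0, b = 5, c = max(c0, min(x[x > 0])))
  })
  a0 <- mean(vapply(starts, `[[`, 0, "a"))
  d0 <- mean(vapply(starts, `[[`, 0, "d"))
  theta0 <- unname(c(a0, d0,
                     vapply(starts, `[[`, 0, "b"),
                     vapply(starts, `[[`, 0, "c")))

  resid_fn <- function(theta) {
    a <- theta[1]; d <- theta[2]
    b <- theta[2 + seq_len(K)]
    cc <- theta[2 + K + seq_len(K)]
    unlist(lapply(seq_len(K), function(k) {
      df <- responses[[k]]
      df$response - fourpl(df$mi, a, d, b[k], abs(cc[k]))
    }), use.names = FALSE)
  }

  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  # info 1-4: converged; 6-8: tolerances at machine limits (as converged as
  # possible); 5 (iteration cap) only passes with a negligible residual
  y_scale <- sum(unlist(lapply(responses, function(df) {
    (df$response - mean(df$response))^2
  })))
  if (fit$info %in% c(0, 9) ||
      (fit$info == 5 && fit$deviance > 1e-9 * max(y_scale, 1))) {
    stop(sprintf(
      "4PL fit did not converge (info %d, best residual SS %.4g, start a=%.3g d=%.3g)",
      fit$info, fit$deviance, a0, d0))
  }
  theta <- unname(fit$par)
  theta[2 + K + seq_len(K)] <- abs(theta[2 + K + seq_len(K)])
  r <- resid_fn(theta)
  n <- length(r)
  p <- length(theta)
  dof <- n - p
  sigma2 <- sum(r^2) / max(dof, 1L)
  J <- .num_jacobian(resid_fn, theta)
  covm <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  tq <- qt(1 - (1 - conf) / 2, max(dof, 1L))

  out <- lapply(seq_len(K), function(k) {
    ci <- theta[2 + K + k]
    se <- if (is.null(covm)) NA_real_ else sqrt(covm[2 + K + k, 2 + K + k])
    rng <- range(responses[[k]]$mi)
    structure(
      list(a = theta[1], d = theta[2], b = theta[2 + k], c = ci,
           c_se = se, c_ci = ci + c(-1, 1) * tq * se, threshold = ci,
           flagged = ci < rng[1] || ci > rng[2],
           residual_ss = sum(r^2), df = dof, n = nrow(responses[[k]]),
           mi_range = rng, shared_plateaus = share_plateaus && K > 1L),
      class = "logistic_fit_4pl"
    )
  })
  names(out) <- names(responses)
  out
}

#' @export
print.logistic_fit_4pl <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit_4pl> a = %.4g, d = %.4g, b = %.4g, c = %.4g (95%% CI %.4g-%.4g)%s\n",
    x$a, x$d, x$b, x$c, x$c_ci[1], x$c_ci[2],
    if (x$flagged) " [c outside data range]" else ""))
  invisible(x)
}

#' Cavitation regime boundaries from a 4PL fit
#'
#' Splits the MI axis into stable / transitional / inertial regimes at the
#' points where the fitted sigmoid completes 5% and 95% of its a-to-d
#' transition.  Closed form: the MI at transition fraction `q` is
#' \eqn{x_q = c\,(q/(1-q))^{1/b}}, so the two boundaries satisfy
#' \eqn{x_{0.05}\, x_{0.95} = c^2} and both collapse onto `c` as
#' \eqn{b \to \infty}.
#'
#' @param fit a `logistic_fit_4pl` (from [fit_4pl()]).
#' @param q transition fraction defining the boundaries (default 0.05).
#' @return List with `stable_upper_mi` and `inertial_lower_mi`.
#' @examples
#' mi <- seq(0.02, 1.2, length.out = 40)
#' f <- fit_4pl(data.frame(mi = mi, response = fourpl(mi, 0, -30, 8, 0.3)))[[1]]
#' classify_regimes(f)   # boundaries ~ (0.208, 0.433)
#' @export
classify_regimes <- function(fit, q = 0.05) {
  stopifnot(inherits(fit, "logistic_fit_4pl"), q > 0, q < 0.5)
  x_at <- function(frac) fit$c * (frac / (1 - frac))^(1 / fit$b)
  bounds <- sort(c(x_at(q), x_at(1 - q)))
  list(stable_upper_mi = bounds[1], inertial_lower_mi = bounds[2])
}
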
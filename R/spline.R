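#' Penalized quintic smoothing spline for displacement data
#'
#' Fits a degree-5 (order-6) penalized B-spline to angular displacement
#' versus time: the basis is built on equally spaced knots spanning the
#' observation window, and a third-order difference penalty on the basis
#' coefficients controls roughness, so straight lines and parabolas pass
#' through unshrunk. The smoothing parameter is chosen by generalized
#' cross-validation (GCV) unless an effective-degrees-of-freedom target is
#' supplied. Velocity and acceleration are later obtained as the exact
#' analytic first and second derivatives of the fitted spline — never as
#' finite differences of the samples.
#'
#' @param series A [cumulative_arc_length()] result (`displacement_series`),
#'   or any list with numeric `times` and `theta_rad` of equal length.
#' @param smoothing `NULL` for GCV selection (default), or a single number
#'   interpreted as a target effective degrees of freedom (must lie in
#'   (3, K] where K is the basis dimension).
#' @param nseg Number of B-spline segments; basis dimension is `nseg + 5`,
#'   capped so it never exceeds the number of observations.
#' @return Object of class `quintic_pspline`: list with `knots`, `coef`,
#'   `lambda`, `edf`, `residual_sd`, `range` (fitted time interval),
#'   `degree = 5`, and the data used. Evaluate with [predict()].
#' @seealso [predict.quintic_pspline()], [differentiate()]
#' @export
fit_quintic_spline <- function(series, smoothing = NULL, nseg = NULL) {
  x <- as.numeric(series$times)
  y <- as.numeric(series$theta_rad)
  n <- length(x)
  if (length(y) != n) stop("times and displacement differ in length")
  if (n < 6L) stop("need at least 6 points to fit a quintic spline, got ", n)
  if (anyDuplicated(x) || any(diff(x) <= 0)) {
    stop("times must be strictly increasing and distinct")
  }
  ord <- 6L # degree 5
  deg <- ord - 1L
  if (is.null(nseg)) nseg <- max(4L, min(n - deg, 30L))
  nseg <- max(1L, min(nseg, n - deg))
  K <- nseg + deg
  rng <- range(x)
  dx <- diff(rng) / nseg
  knots <- rng[1] + dx * seq.int(-deg, nseg + deg)
  B <- splines::splineDesign(knots, x, ord = ord)
  D <- diff(diag(K), differences = 3L)
  P <- crossprod(D)
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)

  fit_at <- function(lambda) {
    M <- BtB + lambda * P
    beta <- solve(M, Bty)
    H_diag_tr <- sum(diag(solve(M, BtB)))
    fitted <- drop(B %*% beta)
    rss <- sum((y - fitted)^2)
    list(beta = drop(beta), edf = H_diag_tr, rss = rss, lambda = lambda)
  }
  # scale-free reference so the lambda grid adapts to the time units
  lam0 <- sum(diag(BtB)) / max(sum(diag(P)), .Machine$double.eps)

  if (is.null(smoothing)) {
    gcv <- function(loglam) {
      f <- fit_at(lam0 * 10^loglam)
      n * f$rss / (n - f$edf)^2
    }
    grid <- seq(-8, 6, by = 0.5)
    vals <- vapply(grid, gcv, numeric(1))
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(gcv, c(lo, hi))
    lambda <- lam0 * 10^opt$minimum
    method <- "GCV"
  } else {
    df_target <- as.numeric(smoothing)
    if (!(df_target > 3 && df_target <= K)) {
      stop("`smoothing` (target edf) must lie in (3, ", K, "]")
    }
    f_edf <- function(loglam) fit_at(lam0 * 10^loglam)$edf - df_target
    lo <- -10
    hi <- 10
    if (f_edf(lo) < 0) {
      lambda <- lam0 * 10^lo
    } else if (f_edf(hi) > 0) {
      lambda <- lam0 * 10^hi
    } else {
      lambda <- lam0 * 10^stats::uniroot(f_edf, c(lo, hi))$root
    }
    method <- "fixed-df"
  }
  f <- fit_at(lambda)
  structure(
    list(
      knots = knots, coef = f$beta, lambda = lambda, edf = f$edf,
      residual_sd = sqrt(max(f$rss, 0) / max(n - f$edf, 1)),
      range = rng, degree = 5L, n = n, method = method,
      times = x, theta_rad = y
    ),
    class = "quintic_pspline"
  )
}

#' Evaluate a fitted quintic spline or its derivatives
#'
#' Evaluation uses the exact derivative of the B-spline basis, so `deriv =
#' 1` and `deriv = 2` are the analytic angular velocity and acceleration
#' of the fitted displacement. Evaluation outside the fitted time interval
#' is an error.
#'
#' @param object A `quintic_pspline`.
#' @param times Times (s) at which to evaluate; defaults to the data times.
#' @param deriv Derivative order: 0 (displacement), 1, or 2.
#' @param ... Unused.
#' @return Numeric vector of spline values.
#' @export
predict.quintic_pspline <- function(object, times = NULL, deriv = 0L, ...) {
  if (is.null(times)) times <- object$times
  deriv <- as.integer(deriv)
  if (!deriv %in% 0:2) stop("`deriv` must be 0, 1, or 2")
  eps <- 1e-12 * max(1, diff(object$range))
  if (any(times < object$range[1] - eps | times > object$range[2] + eps)) {
    stop("evaluation outside the fitted interval [",
         object$range[1], ", ", object$range[2], "]")
  }
  times <- pmin(pmax(times, object$range[1]), object$range[2])
  Bd <- splines::splineDesign(object$knots, times, ord = 6L,
                              derivs = rep(deriv, length(times)))
  drop(Bd %*% object$coef)
}

#' @export
print.quintic_pspline <- function(x, ...) {
  cat(sprintf(
    "<quintic_pspline> n = %d, edf = %.2f (%s), lambda = %.3g, residual sd = %.3g rad\n",
    x$n, x$edf, x$method, x$lambda, x$residual_sd
  ))
  invisible(x)
}
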
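#' Fit a Michaelis-Menten rectangular hyperbola
#'
#' Fits `V = Vmax * S / (Km + S)` -- the saturation curve used to model
#' growth against inorganic iron -- by bounded nonlinear least squares
#' (Levenberg-Marquardt, `Vmax, Km >= 0`). Initialisation is documented
#' and deterministic: `Vmax0 = max(v)` and `Km0` the substrate level at
#' half of `Vmax0`, found by linear interpolation of the response
#' profile (falling back to the median substrate level when the profile
#' never crosses half-max).
#'
#' R-squared is computed on the fitted scale, `1 - SSE/SST`, and adjusted
#' with the Wherry formula `1 - (1 - R2)(n - 1)/(n - p - 1)` with `p = 2`
#' parameters. Non-convergence is reported (warning plus the `converged`
#' flag), never silent.
#'
#' @param s substrate concentration per point, mol L-1 (Fe' in the iron
#'   work).
#' @param v response per point (e.g. growth, cm2 d-1).
#' @param means fit on treatment means instead of per-replicate points.
#' @param max_eval maximum function evaluations.
#' @param tol convergence tolerance passed to the optimizer.
#' @return object of class `mm_fit`: `vmax`, `km`, `r2`, `adj_r2`, `n`,
#'   `converged`, `residuals`, `fitted`, `s`, `v`.
#' @examples
#' s <- c(1, 2, 5, 10, 20, 50, 120)
#' v <- 10 * s / (5 + s)
#' fit_michaelis_menten(s, v)
#' @export
fit_michaelis_menten <- function(s, v, means = FALSE, max_eval = 1e4,
                                 tol = 1e-10) {
  keep <- is.finite(s) & is.finite(v)
  s <- s[keep]; v <- v[keep]
  if (length(s) < 3) {
    stop("need at least 3 points to fit", call. = FALSE)
  }
  if (length(unique(s)) < 2) {
    stop("degenerate input: all substrate values identical", call. = FALSE)
  }
  if (means) {
    vm <- tapply(v, s, mean)
    s <- as.numeric(names(vm)); v <- as.numeric(vm)
    if (length(s) < 3) stop("need at least 3 distinct levels", call. = FALSE)
  }
  vmax0 <- max(v)
  km0 <- mm_km_init(s, v, vmax0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vmax * s / (km + s),
      start = list(vmax = vmax0, km = km0),
      lower = c(0, 0),
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, maxfev = max_eval, ftol = tol, ptol = tol)
    ),
    error = function(e) e
  )
  n <- length(v)
  if (inherits(fit, "error")) {
    warning("Michaelis-Menten fit did not converge: ",
            conditionMessage(fit), call. = FALSE)
    out <- list(vmax = NA_real_, km = NA_real_, r2 = NA_real_,
                adj_r2 = NA_real_, n = n, converged = FALSE,
                residuals = rep(NA_real_, n), fitted = rep(NA_real_, n),
                s = s, v = v)
    class(out) <- "mm_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  fitted_v <- as.numeric(stats::fitted(fit))
  resid_v <- v - fitted_v
  sse <- sum(resid_v^2)
  sst <- sum((v - mean(v))^2)
  r2 <- if (sst <= .Machine$double.eps * max(1, sum(v^2))) {
    if (sse <= .Machine$double.eps) 0 else 0
  } else {
    1 - sse / sst
  }
  p <- 2
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  out <- list(
    vmax = unname(cf["vmax"]), km = unname(cf["km"]),
    r2 = r2, adj_r2 = adj_r2, n = n, converged = TRUE,
    residuals = resid_v, fitted = fitted_v, s = s, v = v
  )
  class(out) <- "mm_fit"
  out
}

# Substrate level at half of vmax0 by interpolation of the mean response
# profile; median(s) when the profile never crosses half-max.
mm_km_init <- function(s, v, vmax0) {
  prof <- tapply(v, s, mean)
  ss <- as.numeric(names(prof)); vv <- as.numeric(prof)
  half <- vmax0 / 2
  if (all(vv < half) || all(vv >= half) || length(ss) < 2) {
    return(max(stats::median(s), .Machine$double.eps))
  }
  cross <- which(vv[-1] >= half & vv[-length(vv)] < half)
  if (length(cross) == 0) {
    return(max(stats::median(s), .Machine$double.eps))
  }
  i <- cross[1]
  frac <- (half - vv[i]) / (vv[i + 1] - vv[i])
  max(ss[i] + frac * (ss[i + 1] - ss[i]), .Machine$double.eps)
}

#' Substrate concentration at a given fraction of saturation
#'
#' For the rectangular hyperbola, the substrate level where the response
#' reaches `fraction * Vmax` is `fraction * Km / (1 - fraction)`: the
#' half-saturation level is Km itself and 90% saturation sits at 9 Km.
#'
#' @param fit an [fit_michaelis_menten()] result (or a bare Km value).
#' @param fraction saturation fraction, strictly between 0 and 1.
#' @return substrate concentration, in the units of the fitted `s`.
#' @examples
#' saturation_concentration(5, fraction = 0.9)  # 45
#' @export
saturation_concentration <- function(fit, fraction = 0.5) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  km <- if (inherits(fit, "mm_fit")) {
    if (!isTRUE(fit$converged)) {
      stop("cannot use a non-converged fit", call. = FALSE)
    }
    fit$km
  } else {
    as.numeric(fit)
  }
  fraction * km / (1 - fraction)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit: V = Vmax * S / (Km + S)\n")
  if (isTRUE(x$converged)) {
    cat(sprintf("  Vmax = %.4g   Km = %.4g\n", x$vmax, x$km))
    cat(sprintf("  n = %d   R2 = %.3f   adjusted R2 = %.3f\n",
                x$n, x$r2, x$adj_r2))
  } else {
    cat("  fit did not converge (n =", x$n, ")\n")
  }
  invisible(x)
}
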
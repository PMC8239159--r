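# Retention-time -> glucose-unit-index calibration.
#
# GUI is regressed on retention time: y = beta0 + beta1 x + ... + betaN x^N
# (or y = beta0 + beta1 log x). Coefficients come from the normal equations
# beta = (X'X)^-1 X'y solved by Gaussian elimination; to tame Vandermonde
# conditioning on minute-scale cubics, the regressor is mean-centred and
# scaled internally and the coefficients are back-transformed to the raw
# scale before reporting.

#' Fit a GUI calibration curve
#'
#' @param points data.frame with columns \code{rt} (minutes) and \code{gu}
#'   (glucose units), typically \code{ladderAssignment(...)[, c("rt","gu")]}
#' @param kind "polynomial" or "logarithmic" (single log term)
#' @param order polynomial degree; default 3 (cubic), ignored for
#'   logarithmic fits
#' @return a \linkS4class{CalibrationModel} with raw-scale coefficients and
#'   the coefficient of determination on the fit points
#' @examples
#' pts <- data.frame(rt = seq(10, 50, length.out = 11), gu = 2:12)
#' fitCalibration(pts)
#' @export
fitCalibration <- function(points, kind = c("polynomial", "logarithmic"),
                           order = 3L) {
  kind <- match.arg(kind)
  if (!all(c("rt", "gu") %in% names(points)))
    stop("points must have columns 'rt' and 'gu'")
  points <- points[base::order(points$rt), c("rt", "gu")]
  x <- points$rt
  y <- points$gu
  if (kind == "logarithmic") {
    if (any(x <= 0)) stop("logarithmic fit requires all retention times > 0")
    x <- log(x)
    order <- 1L
  }
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  if (length(unique(x)) < order + 1L)
    stop("need at least ", order + 1L, " distinct retention times for order ",
         order)

  ctr <- mean(x)
  scl <- stats::sd(x)
  if (!is.finite(scl) || scl == 0) scl <- 1
  z <- (x - ctr) / scl
  X <- outer(z, 0:order, `^`)
  XtX <- crossprod(X)
  beta <- tryCatch(solve(XtX, crossprod(X, y)),
                   error = function(e) stop("normal equations are singular ",
                     "(duplicate retention times or order too high): ",
                     conditionMessage(e)))
  beta <- drop(beta)

  # back-transform: sum_k b_k ((x-c)/s)^k -> raw-scale coefficients via
  # binomial expansion
  raw <- numeric(order + 1L)
  for (k in 0:order) {
    bk <- beta[k + 1L] / scl^k
    for (j in 0:k)
      raw[j + 1L] <- raw[j + 1L] + bk * choose(k, j) * (-ctr)^(k - j)
  }

  fitted <- drop(X %*% beta)
  ssRes <- sum((y - fitted)^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else 1
  new("CalibrationModel", kind = kind, order = order, coefficients = raw,
      rSquared = r2, fitPoints = points, rtRange = range(points$rt))
}

#' Map retention time to GUI
#'
#' Evaluates the fitted calibration polynomial (or logarithmic curve) at the
#' given retention times. Extrapolation beyond the fitted rt range is
#' permitted but flagged via the \code{"extrapolated"} attribute of the
#' result.
#'
#' @param model a \linkS4class{CalibrationModel}
#' @param rt retention time(s) in minutes
#' @return numeric GUI value(s), with logical attribute
#'   \code{"extrapolated"}
#' @export
rtToGUI <- function(model, rt) {
  stopifnot(is(model, "CalibrationModel"))
  x <- rt
  if (model@kind == "logarithmic") {
    if (any(rt <= 0)) stop("logarithmic model requires rt > 0")
    x <- log(rt)
  }
  gui <- drop(outer(x, 0:model@order, `^`) %*% model@coefficients)
  attr(gui, "extrapolated") <- rt < model@rtRange[1L] | rt > model@rtRange[2L]
  gui
}

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: %s (order %d), R^2 = %.6f, %d fit points, rt %.2f-%.2f min\n",
              object@kind, object@order, object@rSquared,
              nrow(object@fitPoints), object@rtRange[1L], object@rtRange[2L]))
  cat("  coefficients:", paste(signif(object@coefficients, 6), collapse = ", "), "\n")
})
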
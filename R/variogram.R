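## Semivariogram models and empirical estimators. The empirical variogram
## (Matheron or Cressie-Hawkins) is an exploratory diagnostic here; parameter
## estimation is by REML (see reml_fit), not by fitting curves to the bins.

#' Construct a semivariogram model
#'
#' @param family \code{"exponential"}, \code{"spherical"} or \code{"nugget"}
#' @param c0 nugget variance ((ug/L)^2)
#' @param c1 partial sill ((ug/L)^2); total sill is \code{c0 + c1}
#' @param a distance parameter (km); for the exponential family the
#'   effective range is about \code{3a}, for the spherical it is \code{a}
#' @param mu constant mean (ug/L), optional (filled by \code{\link{reml_fit}})
#' @param loglik REML log-likelihood at the optimum, optional
#' @return object of class \code{variogram_model}
#' @export
variogram_model <- function(family = c("exponential", "spherical", "nugget"),
                            c0, c1, a = NA_real_, mu = NA_real_,
                            loglik = NA_real_) {
  family <- match.arg(family)
  stopifnot(c0 >= 0, c1 >= 0)
  if (family != "nugget" && !(is.finite(a) && a > 0)) {
    stop("distance parameter `a` must be > 0 for family '", family, "'")
  }
  if (family == "nugget") a <- NA_real_
  structure(list(family = family, c0 = c0, c1 = c1, a = a, mu = mu,
                 loglik = loglik),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram model: %s\n", x$family))
  cat(sprintf("  nugget c0 = %.4g   partial sill c1 = %.4g", x$c0, x$c1))
  if (!is.na(x$a)) cat(sprintf("   a = %.4g km", x$a))
  cat("\n")
  if (!is.na(x$mu)) cat(sprintf("  mean = %.4g", x$mu))
  if (!is.na(x$loglik)) cat(sprintf("   REML loglik = %.4f", x$loglik))
  if (!is.na(x$mu) || !is.na(x$loglik)) cat("\n")
  invisible(x)
}

#' Semivariance of a model at distance h
#'
#' \code{gamma(0) = 0}; for \code{h > 0}: exponential
#' \code{c0 + c1*(1 - exp(-h/a))}; spherical
#' \code{c0 + c1*(1.5*h/a - 0.5*(h/a)^3)} up to \code{a}, then
#' \code{c0 + c1}; pure nugget \code{c0}.
#'
#' @param model a \code{\link{variogram_model}}
#' @param h distance(s), km, >= 0
#' @return semivariance(s), ((ug/L)^2)
#' @export
model_gamma <- function(model, h) {
  if (any(h < 0)) stop("negative lag distance")
  g <- model$c0 + model$c1 * (1 - correlogram(h, model$family, model$a))
  g[h == 0] <- 0
  g
}

## Semivariance between distinct records at separation h >= 0: the nugget
## applies to every pair of distinct measurements, including coincident ones
## (right-limit of model_gamma). Used to build kriging/covariance matrices.
record_gamma <- function(model, h) {
  model$c0 + model$c1 * (1 - correlogram(h, model$family, model$a))
}

#' Empirical semivariogram
#'
#' Bins point pairs by separation distance and estimates the semivariance
#' per bin by either the classical Matheron moment estimator,
#' \deqn{\hat\gamma(h) = \frac{1}{2N(h)} \sum (z_i - z_j)^2,}
#' or the Cressie-Hawkins robust estimator
#' \deqn{\hat\gamma(h) = \frac{1}{2}\,
#'   \frac{\bigl[\frac{1}{N(h)}\sum |z_i - z_j|^{1/2}\bigr]^4}
#'        {0.457 + 0.494/N(h)},}
#' which damps the influence of outliers in the upper tail.
#'
#' @param records survey data frame (columns \code{x}, \code{y}, \code{se})
#' @param estimator \code{"matheron"} or \code{"cressie_hawkins"}
#' @param bin_width lag bin width (km)
#' @param max_lag maximum lag (km); default half the maximum inter-point
#'   distance
#' @return object of class \code{empirical_variogram}: data frame with
#'   \code{lag_mid}, \code{gamma_hat}, \code{n_pairs} plus attributes
#' @export
empirical_variogram <- function(records,
                                estimator = c("matheron", "cressie_hawkins"),
                                bin_width = 1, max_lag = NULL) {
  estimator <- match.arg(estimator)
  if (bin_width <= 0) stop("bin_width must be positive")
  x <- records$x; y <- records$y; z <- records$se
  n <- length(z)
  if (n < 2L) stop("need at least 2 records")
  d <- dist(cbind(x, y))
  if (max(d) == 0) stop("all points coincident; no spatial lags available")
  if (is.null(max_lag)) max_lag <- max(d) / 2
  dz <- dist(matrix(z, ncol = 1))  # |z_i - z_j| over the same pair ordering
  dv <- as.vector(d)
  dzv <- as.vector(dz)
  keep <- dv > 0 & dv <= max_lag
  dv <- dv[keep]; dzv <- dzv[keep]
  breaks <- seq(0, max_lag, by = bin_width)
  if (breaks[length(breaks)] < max_lag - 1e-12) breaks <- c(breaks, max_lag)
  bin <- cut(dv, breaks, include.lowest = FALSE, labels = FALSE)
  nb <- length(breaks) - 1L
  gamma_hat <- rep(NA_real_, nb)
  n_pairs <- integer(nb)
  for (b in seq_len(nb)) {
    sel <- which(bin == b)
    n_pairs[b] <- length(sel)
    if (!length(sel)) next
    if (estimator == "matheron") {
      gamma_hat[b] <- mean(dzv[sel]^2) / 2
    } else {
      m <- mean(sqrt(dzv[sel]))
      gamma_hat[b] <- 0.5 * m^4 / (0.457 + 0.494 / length(sel))
    }
  }
  out <- data.frame(lag_mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                    gamma_hat = gamma_hat, n_pairs = n_pairs)
  structure(out, estimator = estimator, bin_width = bin_width,
            max_lag = max_lag, class = c("empirical_variogram", "data.frame"))
}

#' @export
print.empirical_variogram <- function(x, ...) {
  cat(sprintf("empirical variogram (%s), %d bins to %.1f km\n",
              attr(x, "estimator"), nrow(x), attr(x, "max_lag")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.empirical_variogram <- function(x, model = NULL, ...) {
  ok <- x$n_pairs > 0
  graphics::plot(x$lag_mid[ok], x$gamma_hat[ok], xlab = "lag (km)",
                 ylab = expression(gamma(h)), pch = 16, ...)
  if (!is.null(model)) {
    hh <- seq(0, max(x$lag_mid), length.out = 200)
    graphics::lines(hh, model_gamma(model, hh))
  }
  invisible(x)
}
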
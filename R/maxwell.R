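# Ideal-chain (Maxwell) reference state: the end-to-end distance R of an
# ideal chain of m Kuhn segments of length b is Maxwell-distributed,
#
#   M_m(R, b) = 4 pi R^2 (3 / (2 pi b^2 m))^(3/2) exp(-3 R^2 / (2 b^2 m)),
#
# i.e. each Cartesian component is Gaussian with variance b^2 m / 3. The
# single scale parameter b (the Kuhn length) is fitted per separation m by
# maximum likelihood; the Fisher information at the optimum gives the
# uncertainty sigma_b = b / sqrt(6 n).

#' Maxwell end-to-end distance density
#'
#' @param R distance(s), Angstrom, >= 0.
#' @param b Kuhn length, Angstrom, > 0.
#' @param m number of segments (sequence separation), >= 1.
#' @return density values (1/Angstrom).
#' @export
maxwell_pdf <- function(R, b, m) {
  if (any(R < 0)) stop("R must be non-negative")
  if (b <= 0) stop("Kuhn length b must be positive")
  if (m < 1) stop("m must be >= 1")
  s2 <- b^2 * m
  4 * pi * R^2 * (3 / (2 * pi * s2))^1.5 * exp(-3 * R^2 / (2 * s2))
}

#' Draw end-to-end distances from the Maxwell distribution
#'
#' Each Cartesian component is N(0, b^2 m / 3), so R^2 = (b^2 m / 3) * chi2_3.
#'
#' @param n sample size.
#' @param b Kuhn length, Angstrom.
#' @param m number of segments.
#' @param seed optional seed (local to this call).
#' @return numeric vector of n distances.
#' @export
sample_maxwell <- function(n, b, m, seed = NULL) {
  stopifnot(b > 0, m >= 1, n >= 1)
  with_seed(seed, b * sqrt(m / 3) * sqrt(stats::rchisq(n, df = 3)))
}

#' Maximum-likelihood Kuhn length for one fragment set
#'
#' The ML estimator has the closed form `b_hat = sqrt(mean(R^2) / m)`
#' (stationarity of the Maxwell log-likelihood in b); the Fisher-information
#' uncertainty is `sigma_b = b_hat / sqrt(6 n)`.
#'
#' @param fs a `fragment_set`, or a numeric vector of distances (then `m`
#'   must be given).
#' @param m sequence separation (only when `fs` is a bare numeric vector).
#' @param level coarse-graining label carried through to the result.
#' @return An object of class `maxwell_fit`: list with `m`, `b`, `sigma_b`,
#'   `n`, `level`.
#' @export
fit_kuhn_length <- function(fs, m = NULL, level = "CA") {
  if (inherits(fs, "fragment_set")) {
    x <- fs$distances; m <- fs$m; level <- fs$level
  } else {
    x <- as.numeric(fs)
    if (is.null(m)) stop("`m` required when passing raw distances")
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 distances to fit a Kuhn length")
  if (any(x <= 0)) stop("all distances must be positive")
  b <- sqrt(mean(x^2) / m)
  structure(list(m = as.integer(m), b = b, sigma_b = b / sqrt(6 * n),
                 n = n, level = level),
            class = "maxwell_fit")
}

#' @export
print.maxwell_fit <- function(x, ...) {
  cat(sprintf("Maxwell fit (%s, m = %d): b = %.4f +/- %.4f A  (n = %d)\n",
              x$level, x$m, x$b, x$sigma_b, x$n))
  invisible(x)
}

#' Plateau Kuhn length over a separation range
#'
#' The Flory-regime Kuhn length b* is the unweighted arithmetic mean of b(m)
#' over the plateau range (default 70-90); its uncertainty is the standard
#' error of that mean.
#'
#' @param fits list of `maxwell_fit`, one per m.
#' @param m_range inclusive range `c(lo, hi)`; every m in it must be present.
#' @return list of class `plateau_estimate` with `b_star`, `sigma_b_star`,
#'   `m_range`, `b_by_m`.
#' @export
plateau_kuhn_length <- function(fits, m_range = c(70L, 90L)) {
  ms <- vapply(fits, function(f) f$m, 0L)
  bs <- vapply(fits, function(f) f$b, 0)
  want <- seq.int(m_range[1L], m_range[2L])
  if (!all(want %in% ms))
    stop("incomplete plateau range: missing m = ",
         paste(setdiff(want, ms), collapse = ", "))
  sel <- match(want, ms)
  b <- bs[sel]
  k <- length(b)
  structure(list(b_star = mean(b),
                 sigma_b_star = if (k > 1) stats::sd(b) / sqrt(k) else 0,
                 m_range = m_range,
                 b_by_m = stats::setNames(b, want)),
            class = "plateau_estimate")
}

#' @export
print.plateau_estimate <- function(x, ...) {
  cat(sprintf("Kuhn plateau b* = %.4f +/- %.4f A over m in [%d, %d]\n",
              x$b_star, x$sigma_b_star, x$m_range[1L], x$m_range[2L]))
  invisible(x)
}

#' Thermal scaling exponent from mean end-to-end distances
#'
#' Least-squares slope of `log <R>` against `log m` over the fit range:
#' nu = 1/2 signals ideal-chain (Flory-regime) statistics, 1/3 compact
#' globules.
#'
#' @param mean_R_by_m named numeric vector (names are m) or data.frame with
#'   columns `m` and `mean_R`.
#' @param fit_m_range inclusive range of m used in the fit (default 70-90).
#' @return list of class `scaling_fit` with `nu`, `intercept` (log-space),
#'   `fit_m_range`, `n_points`.
#' @export
scaling_exponent <- function(mean_R_by_m, fit_m_range = c(70L, 90L)) {
  if (is.data.frame(mean_R_by_m)) {
    m <- mean_R_by_m$m; r <- mean_R_by_m$mean_R
  } else {
    m <- as.numeric(names(mean_R_by_m)); r <- as.numeric(mean_R_by_m)
  }
  keep <- m >= fit_m_range[1L] & m <= fit_m_range[2L] & !is.na(r)
  m <- m[keep]; r <- r[keep]
  if (length(m) < 3L) stop("need at least 3 (m, <R>) points in the fit range")
  if (any(r <= 0)) stop("mean distances must be positive")
  fit <- stats::lm(log(r) ~ log(m))
  structure(list(nu = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 fit_m_range = fit_m_range, n_points = length(m)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Thermal exponent nu = %.4f (fit on %d points, m in [%d, %d])\n",
              x$nu, x$n_points, x$fit_m_range[1L], x$fit_m_range[2L]))
  invisible(x)
}

#' Write Maxwell fit tables as TSV
#'
#' Columns: level, m, n, b, sigma_b.
#'
#' @param fits list of `maxwell_fit`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_kuhn_fits <- function(fits, path) {
  tab <- data.frame(level = vapply(fits, function(f) f$level, ""),
                    m = vapply(fits, function(f) f$m, 0L),
                    n = vapply(fits, function(f) f$n, 0L),
                    b = vapply(fits, function(f) f$b, 0),
                    sigma_b = vapply(fits, function(f) f$sigma_b, 0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
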
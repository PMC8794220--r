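# Dataset pruning: keep only chains whose size scales like a compact globule,
# Rg(N) = a * N^(1/3), and quantify tangent-vector decorrelation along the
# chain (the observation motivating the lower fragment-length cut-off).

#' Fit the globular scaling law and flag outliers
#'
#' Fits `Rg = a * N^(1/3)` by least squares in log space (the exponent is held
#' at 1/3; only the prefactor `a` is free) and discards every chain whose
#' log-residual exceeds `k_sigma` standard deviations of the residual
#' distribution. The fit-and-discard is a single pass: `a` and the residual
#' standard deviation are not re-estimated after discarding.
#'
#' @param points data.frame with columns `N` (residue count) and `Rg`
#'   (Angstrom); an optional `id` column labels the chains.
#' @param k_sigma discard threshold in residual standard deviations
#'   (default 3).
#' @return An object of class `globularity_fit`: list with prefactor `a`
#'   (Angstrom), `residual_sd` (log-space), `retained_ids`, `discarded_ids`,
#'   and the per-chain `table` (id, N, Rg, log_residual, retained).
#' @export
fit_globularity <- function(points, k_sigma = 3) {
  points <- as.data.frame(points)
  if (!all(c("N", "Rg") %in% names(points)))
    stop("`points` needs columns N and Rg")
  if (nrow(points) < 3L)
    stop("globularity fit is underdetermined with fewer than 3 chains")
  if (any(points$N < 2) || any(points$Rg <= 0))
    stop("need N >= 2 and Rg > 0 for all chains")
  if (is.null(points$id)) points$id <- as.character(seq_len(nrow(points)))

  # log Rg = log a + (1/3) log N  =>  intercept-only regression
  resid0 <- log(points$Rg) - log(points$N) / 3
  log_a <- mean(resid0)
  r <- resid0 - log_a
  s <- stats::sd(r)
  retained <- if (is.na(s) || s == 0) rep(TRUE, nrow(points))
              else abs(r) <= k_sigma * s
  tab <- data.frame(id = points$id, N = points$N, Rg = points$Rg,
                    log_residual = r, retained = retained,
                    stringsAsFactors = FALSE)
  structure(list(a = exp(log_a), residual_sd = if (is.na(s)) 0 else s,
                 k_sigma = k_sigma,
                 retained_ids = points$id[retained],
                 discarded_ids = points$id[!retained],
                 table = tab),
            class = "globularity_fit")
}

#' @export
print.globularity_fit <- function(x, ...) {
  cat(sprintf("Globularity fit Rg = a N^(1/3): a = %.3f A, sd(log resid) = %.4f\n",
              x$a, x$residual_sd))
  cat(sprintf("  retained %d, discarded %d (|log residual| > %g sd)\n",
              length(x$retained_ids), length(x$discarded_ids), x$k_sigma))
  invisible(x)
}

#' Write the globularity report as TSV
#'
#' One row per chain: id, N, Rg, log-residual, retained/discarded.
#'
#' @param fit a `globularity_fit`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_globularity_report <- function(fit, path) {
  stopifnot(inherits(fit, "globularity_fit"))
  tab <- fit$table
  tab$status <- ifelse(tab$retained, "retained", "discarded")
  utils::write.table(tab[c("id", "N", "Rg", "log_residual", "status")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tangent-tangent correlation along the chain
#'
#' The tangent at residue i is the central difference of the CA coordinates,
#' `t_i = CA(i+1) - CA(i-1)`, defined for interior residues only (the two
#' chain ends are skipped, not one-sided). For each sequence separation
#' `m = 0..m_max` the mean cosine of the angle between `t_i` and `t_(i+m)`
#' is averaged over all valid residue pairs of all chains. Decay of this
#' correlation to zero marks the separation beyond which local chain
#' stiffness (secondary structure) no longer biases fragment statistics.
#'
#' @param chains a chain, structure, or list of either.
#' @param m_max largest separation reported.
#' @return An object of class `tangent_correlation`: data.frame with columns
#'   `m`, `mean_cosine`, `count`.
#' @export
tangent_correlation <- function(chains, m_max = 40L) {
  chains <- as_chain_list(chains)
  chains <- Filter(function(ch) ch$N >= 3L, chains)
  if (length(chains) == 0L)
    stop("no chain with >= 3 residues; tangent vectors undefined")
  sums <- numeric(m_max + 1L)
  cnts <- integer(m_max + 1L)
  for (ch in chains) {
    ca <- ch$ca
    ok <- stats::complete.cases(ca)
    n <- ch$N
    tg <- ca[3:n, , drop = FALSE] - ca[1:(n - 2), , drop = FALSE]
    tok <- ok[3:n] & ok[1:(n - 2)]
    nrm <- sqrt(rowSums(tg^2))
    tok <- tok & nrm > 0
    tg <- tg / ifelse(nrm > 0, nrm, 1)
    nt <- nrow(tg)
    for (m in 0:min(m_max, nt - 1L)) {
      i <- seq_len(nt - m)
      valid <- tok[i] & tok[i + m]
      if (!any(valid)) next
      cosv <- rowSums(tg[i, , drop = FALSE] * tg[i + m, , drop = FALSE])[valid]
      sums[m + 1L] <- sums[m + 1L] + sum(cosv)
      cnts[m + 1L] <- cnts[m + 1L] + length(cosv)
    }
  }
  out <- data.frame(m = 0:m_max,
                    mean_cosine = ifelse(cnts > 0, sums / cnts, NA_real_),
                    count = cnts)
  class(out) <- c("tangent_correlation", "data.frame")
  out
}
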
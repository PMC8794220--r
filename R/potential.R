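# Boltzmann inversion against the ideal-chain reference and downstream
# analysis of the resulting statistical potentials.
#
# For each sequence separation m the potential of mean force (in units of
# kB*T = 1) is
#
#   V_m(R | b, w) = -ln( E_m(R, w) / M_m(R, b) ),
#
# the R-independent partition-function ratio being dropped, so every curve
# carries an arbitrary additive constant ("gauge"). Curves are averaged
# pointwise over m, either in the Flory plateau (70-90) or over the broad
# Gaussian range (30-90).

#' Boltzmann inversion of one empirical density
#'
#' Evaluates `V(R) = -ln(E(R)/M_m(R, b))` on the grid points where the
#' empirical density is statistically supported: a point is defined only
#' where the density implies an expected count of at least `min_count`
#' samples per grid bin, which keeps log-of-noise spikes out of the curve.
#' Undefined points are `NA`, never +/-Inf.
#'
#' @param E an `empirical_density`.
#' @param ref a `maxwell_fit` for the same m and level.
#' @param min_count support threshold (expected samples per grid bin,
#'   default 5).
#' @return object of class `potential_curve`: list with `grid`, `V`,
#'   `defined`, `m`, `level`, `b`, `w`, `n`.
#' @export
boltzmann_inversion <- function(E, ref, min_count = 5) {
  stopifnot(inherits(E, "empirical_density"), inherits(ref, "maxwell_fit"))
  if (!is.na(E$m) && E$m != ref$m)
    stop("separation mismatch: density has m = ", E$m,
         ", reference has m = ", ref$m)
  if (!is.na(E$level) && !is.na(ref$level) && E$level != ref$level)
    stop("coarse-graining level mismatch between density and reference")
  grid <- E$grid
  dr <- stats::median(diff(grid))
  M <- maxwell_pdf(grid, ref$b, ref$m)
  defined <- is.finite(E$density) & (E$density * E$n * dr >= min_count) & M > 0
  V <- rep(NA_real_, length(grid))
  V[defined] <- -log(E$density[defined] / M[defined])
  structure(list(grid = grid, V = V, defined = defined, m = ref$m,
                 level = ref$level, b = ref$b, w = E$w, n = E$n),
            class = "potential_curve")
}

#' Average per-m potential curves into a statistical potential
#'
#' Pointwise mean and population standard deviation over the per-m curves,
#' restricted to grid points where at least `min_fraction` of the curves are
#' defined (default: all of them, so the average is never extrapolated into
#' unsupported territory).
#'
#' @param curves list of `potential_curve` sharing one grid.
#' @param m_range optional inclusive range used to subset the curves.
#' @param kind label: `"flory_70_90"` (plateau average, V*) or
#'   `"broad_30_90"` (broad average over the Gaussian range).
#' @param min_fraction minimum fraction of curves defined at a grid point.
#' @param pair optional terminal residue-type pair label, e.g.
#'   `c("CYS", "CYS")`.
#' @return object of class `statistical_potential`: `grid`, `average`,
#'   `spread` (population sd across m), `per_m` (matrix, rows = m),
#'   `m_values`, `level`, `kind`, `pair`.
#' @export
average_potential <- function(curves, m_range = NULL,
                              kind = c("flory_70_90", "broad_30_90"),
                              min_fraction = 1, pair = NULL) {
  kind <- match.arg(kind)
  if (length(curves) == 0L) stop("no potential curves to average")
  ms <- vapply(curves, function(cv) cv$m, 0L)
  if (!is.null(m_range)) {
    keep <- ms >= m_range[1L] & ms <= m_range[2L]
    if (!any(keep)) stop("no curves inside the requested m range")
    curves <- curves[keep]; ms <- ms[keep]
  }
  grid <- curves[[1L]]$grid
  for (cv in curves)
    if (length(cv$grid) != length(grid) || any(cv$grid != grid))
      stop("curves must share a common grid")
  mat <- do.call(rbind, lapply(curves, function(cv) cv$V))
  rownames(mat) <- ms
  frac <- colMeans(!is.na(mat))
  ok <- frac >= min_fraction - 1e-12 & frac > 0
  avg <- rep(NA_real_, length(grid))
  spr <- rep(NA_real_, length(grid))
  avg[ok] <- colMeans(mat[, ok, drop = FALSE], na.rm = TRUE)
  spr[ok] <- sqrt(colMeans(
    sweep(mat[, ok, drop = FALSE], 2L, avg[ok])^2, na.rm = TRUE))
  structure(list(grid = grid, average = avg, spread = spr, per_m = mat,
                 m_values = ms, level = curves[[1L]]$level, kind = kind,
                 pair = pair),
            class = "statistical_potential")
}

#' @export
print.statistical_potential <- function(x, ...) {
  ndef <- sum(!is.na(x$average))
  cat(sprintf("<statistical_potential %s%s> %d curves (m %d-%d), %d/%d grid points defined\n",
              ifelse(is.na(x$level), "?", x$level),
              if (!is.null(x$pair)) paste0(" ", paste(x$pair, collapse = "-"))
              else "",
              length(x$m_values), min(x$m_values), max(x$m_values),
              ndef, length(x$grid)))
  invisible(x)
}

# (grid, values, spread) from the objects accepted by the analysis helpers
as_curve <- function(x) {
  if (inherits(x, "statistical_potential"))
    list(grid = x$grid, values = x$average, spread = x$spread)
  else if (inherits(x, "potential_curve"))
    list(grid = x$grid, values = x$V, spread = NULL)
  else if (is.list(x) && !is.null(x$grid))
    list(grid = x$grid,
         values = if (!is.null(x$values)) x$values else x$V,
         spread = x$spread)
  else stop("cannot interpret input as a potential curve")
}

#' Locate local minima of a potential curve
#'
#' The curve is lightly smoothed (moving average, 3 grid points) for
#' detection; a minimum is a grid point strictly below both neighbours.
#' Positions and depths are refined by parabolic interpolation through the
#' three raw grid values around each detected minimum. With
#' `significant_only = TRUE`, minima shallower than the local spread across
#' m are suppressed (signal-above-noise rule used in pipeline reports).
#'
#' @param sp a `statistical_potential`, `potential_curve`, or list with
#'   `grid` and `values`.
#' @param smooth_window moving-average window (grid points, odd; default 3).
#' @param significant_only keep only minima with |depth| above the local
#'   spread (requires spread information).
#' @return data.frame of class `potential_minima` with columns `position`
#'   (Angstrom) and `value` (kB*T), sorted by position.
#' @export
find_minima <- function(sp, smooth_window = 3L, significant_only = FALSE) {
  cv <- as_curve(sp)
  grid <- cv$grid; v <- cv$values
  out <- data.frame(position = numeric(0), value = numeric(0))
  runs <- split(seq_along(v), cumsum(is.na(v)))
  for (run in runs) {
    run <- run[!is.na(v[run])]
    if (length(run) < 5L) next
    g <- grid[run]; y <- v[run]
    half <- (smooth_window - 1L) %/% 2L
    ys <- y
    if (half > 0L) {
      sm <- stats::filter(y, rep(1 / smooth_window, smooth_window),
                          sides = 2L)
      ys[!is.na(sm)] <- sm[!is.na(sm)]
    }
    idx <- which(diff(sign(diff(ys))) > 0) + 1L
    for (i in idx) {
      # refine on the raw values at the local argmin near the detected point
      lo <- max(2L, i - 1L); hi <- min(length(y) - 1L, i + 1L)
      i0 <- (lo:hi)[which.min(y[lo:hi])]
      y0 <- y[i0 - 1L]; y1 <- y[i0]; y2 <- y[i0 + 1L]
      if (!(y1 <= y0 && y1 <= y2)) next
      denom <- y0 - 2 * y1 + y2
      off <- if (denom > 0) 0.5 * (y0 - y2) / denom else 0
      off <- max(-1, min(1, off))
      dg <- g[2L] - g[1L]
      pos <- g[i0] + off * dg
      val <- y1 - 0.25 * (y0 - y2) * off
      out <- rbind(out, data.frame(position = pos, value = val))
      if (significant_only && !is.null(cv$spread)) {
        spr <- cv$spread[run[i0]]
        if (!is.na(spr) && abs(val) <= spr)
          out <- out[-nrow(out), , drop = FALSE]
      }
    }
  }
  out <- out[!duplicated(round(out$position, 6)), , drop = FALSE]
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("potential_minima", "data.frame")
  out
}

#' Fit the short-range repulsive power law
#'
#' Least-squares line of `ln V` against `ln R` over the fit window; the slope
#' is the repulsion exponent. The default window runs from the smallest
#' defined grid point to the distance where V first drops below 1 kB*T
#' (the "short-range repulsive part"). All V in the window must be positive.
#'
#' @param sp a `statistical_potential`, `potential_curve`, or list with
#'   `grid`/`values`.
#' @param fit_range optional `c(R_lo, R_hi)` window (Angstrom).
#' @return list of class `repulsion_fit` with `exponent`, `prefactor`,
#'   `fit_range`, `n_points`.
#' @export
fit_repulsive_power_law <- function(sp, fit_range = NULL) {
  cv <- as_curve(sp)
  grid <- cv$grid; v <- cv$values
  def <- which(!is.na(v) & grid > 0)
  if (length(def) < 3L) stop("potential curve has too few defined points")
  if (is.null(fit_range)) {
    lo <- grid[def[1L]]
    below <- def[v[def] < 1]
    hi <- if (length(below)) grid[below[1L]] else grid[def[length(def)]]
    if (hi <= lo) stop("cannot determine a default repulsive window; ",
                       "pass fit_range explicitly")
    fit_range <- c(lo, hi)
  }
  sel <- def[grid[def] >= fit_range[1L] & grid[def] <= fit_range[2L]]
  if (length(sel) < 3L) stop("fewer than 3 defined points in the fit range")
  if (any(v[sel] <= 0))
    stop("V <= 0 inside the fit range; shrink the upper bound to the ",
         "repulsive region")
  fit <- stats::lm(log(v[sel]) ~ log(grid[sel]))
  structure(list(exponent = unname(coef(fit)[2L]),
                 prefactor = unname(exp(coef(fit)[1L])),
                 fit_range = fit_range, n_points = length(sel)),
            class = "repulsion_fit")
}

#' @export
print.repulsion_fit <- function(x, ...) {
  cat(sprintf("Short-range repulsion: V ~ %.3g * R^(%.3f), window [%.2f, %.2f] A (%d pts)\n",
              x$prefactor, x$exponent, x$fit_range[1L], x$fit_range[2L],
              x$n_points))
  invisible(x)
}

#' Derive a sequence-dependent statistical potential for one residue pair
#'
#' Restricts every fragment set to fragments whose terminal residues form
#' the requested unordered pair, then reruns the whole per-m derivation on
#' the restricted sets: Kuhn-length ML fit, bandwidth (from the scaling
#' model, or per-set CV when no model is given), KDE, Boltzmann inversion,
#' and finally the broad average over the surviving separations.
#' Separations with fewer than `min_count_per_m` restricted fragments are
#' dropped (and recorded in the result).
#'
#' @param fsets named list of `fragment_set` with terminal types (as from
#'   [collect_distances]).
#' @param aa1,aa2 3-letter codes of the terminal pair.
#' @param bw_model optional `bandwidth_model`; if `NULL`, bandwidths are
#'   cross-validated per restricted set.
#' @param m_range inclusive separation range for the broad average
#'   (default 30-90).
#' @param min_count_per_m minimum restricted-fragment count per separation
#'   (default 50).
#' @param grid shared distance grid.
#' @param min_support_count support threshold passed to
#'   [boltzmann_inversion].
#' @param seed seed for per-set bandwidth CV when `bw_model` is `NULL`.
#' @return a `statistical_potential` with `pair` set; dropped separations in
#'   attribute `"dropped_m"`.
#' @export
derive_sequence_dependent <- function(fsets, aa1, aa2, bw_model = NULL,
                                      m_range = c(30L, 90L),
                                      min_count_per_m = 50L,
                                      grid = default_distance_grid(),
                                      min_support_count = 5, seed = 1L) {
  ms <- as.integer(names(fsets))
  keep <- ms >= m_range[1L] & ms <= m_range[2L]
  fsets <- fsets[keep]; ms <- ms[keep]
  curves <- list(); dropped <- integer(0)
  for (k in seq_along(fsets)) {
    rset <- filter_by_terminal_types(fsets[[k]], aa1, aa2)
    if (rset$n < min_count_per_m) { dropped <- c(dropped, ms[k]); next }
    ref <- fit_kuhn_length(rset)
    w <- if (!is.null(bw_model)) predict_bandwidth(bw_model, rset$n)
         else cross_validate_bandwidth(rset, seed = seed)
    E <- empirical_density(rset, w = w, grid = grid)
    curves[[length(curves) + 1L]] <-
      boltzmann_inversion(E, ref, min_count = min_support_count)
  }
  if (length(curves) == 0L)
    stop("insufficient statistics for pair ", aa1, "-", aa2,
         ": no separation reaches ", min_count_per_m, " fragments")
  sp <- average_potential(curves, kind = "broad_30_90",
                          pair = c(toupper(aa1), toupper(aa2)))
  attr(sp, "dropped_m") <- dropped
  sp
}

# interpolate one potential curve at distances r; values outside the defined
# support are clamped to the nearest defined boundary value
lookup_potential <- function(grid, v, r) {
  def <- which(!is.na(v))
  if (length(def) == 0L) return(list(V = rep(NA_real_, length(r)),
                                     clamped = rep(FALSE, length(r))))
  glo <- grid[def[1L]]; ghi <- grid[def[length(def)]]
  clamped <- r < glo | r > ghi
  rc <- pmin(pmax(r, glo), ghi)
  V <- stats::approx(grid[def], v[def], xout = rc, rule = 2)$y
  list(V = V, clamped = clamped)
}

#' Score a whole chain with a statistical potential
#'
#' Computes the pairwise total score `V_tot = sum_{i<j} V_{|j-i|}(R_ij)`
#' over all residue pairs whose sequence separation is supported by the
#' potential: with per-m curves, each separation uses its own curve; with an
#' average-only potential, the average curve is applied to every separation
#' inside its m range. Pairs at unsupported separations are skipped and
#' counted; distances outside a curve's defined support contribute the
#' nearest defined boundary value and are flagged.
#'
#' @param chain an `fr_chain`.
#' @param sp a `statistical_potential`.
#' @param level coarse-graining level for the pair distances; must match the
#'   potential's level when the latter is known.
#' @param use_per_m use the per-m curves when available (default TRUE).
#' @return list of class `total_score`: `v_tot`, `contributions` (data.frame
#'   i, j, m, R, V, clamped), `n_pairs_skipped`.
#' @export
score_structure <- function(chain, sp, level = NULL, use_per_m = TRUE) {
  stopifnot(inherits(chain, "fr_chain"),
            inherits(sp, "statistical_potential"))
  if (is.null(level)) level <- sp$level
  level <- match_level(level)
  if (!is.na(sp$level) && level != sp$level)
    stop("level mismatch: potential is ", sp$level, ", scoring requested at ",
         level)
  per_m <- use_per_m && !is.null(sp$per_m)
  supported <- if (per_m) sp$m_values
               else seq.int(min(sp$m_values), max(sp$m_values))
  supported <- supported[supported <= chain$N - 1L]
  n_skipped <- chain$N * (chain$N - 1L) / 2 -
    sum(pmax(0L, chain$N - supported))
  contr <- list()
  for (m in supported) {
    i <- seq_len(chain$N - m)
    if (level == "CA") {
      r <- sqrt(rowSums((chain$ca[i, , drop = FALSE] -
                         chain$ca[i + m, , drop = FALSE])^2))
    } else {
      r <- vapply(i, function(ii)
        end_to_end_distance(chain_residue(chain, ii),
                            chain_residue(chain, ii + m), level), numeric(1))
    }
    v <- if (per_m) sp$per_m[as.character(m), ] else sp$average
    lk <- lookup_potential(sp$grid, v, r)
    contr[[length(contr) + 1L]] <-
      data.frame(i = i, j = i + m, m = m, R = r, V = lk$V,
                 clamped = lk$clamped)
  }
  contr <- do.call(rbind, contr)
  ok <- !is.na(contr$V)
  structure(list(v_tot = sum(contr$V[ok]), contributions = contr,
                 n_pairs_skipped = n_skipped + sum(!ok)),
            class = "total_score")
}

#' @export
print.total_score <- function(x, ...) {
  cat(sprintf("V_tot = %.4f kT over %d pairs (%d skipped, %d clamped)\n",
              x$v_tot, sum(!is.na(x$contributions$V)), x$n_pairs_skipped,
              sum(x$contributions$clamped)))
  invisible(x)
}

#' Write a statistical potential as TSV with JSON sidecar
#'
#' The TSV has columns R, V_mean, V_sd, n_curves, with a `#`-prefixed header
#' recording level, kind, m values and pair; the sidecar (same path with
#' `.json` appended) records minima and the short-range power-law fit when
#' they can be computed.
#'
#' @param sp a `statistical_potential`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_potential <- function(sp, path) {
  stopifnot(inherits(sp, "statistical_potential"))
  n_curves <- colSums(!is.na(sp$per_m))
  hdr <- sprintf("# level=%s kind=%s m=%s%s", sp$level, sp$kind,
                 paste(range(sp$m_values), collapse = "-"),
                 if (!is.null(sp$pair))
                   paste0(" pair=", paste(sp$pair, collapse = "-")) else "")
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  suppressWarnings(utils::write.table(
    data.frame(R = sp$grid, V_mean = sp$average, V_sd = sp$spread,
               n_curves = n_curves),
    path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  meta <- list(level = sp$level, kind = sp$kind,
               m_values = sp$m_values, pair = sp$pair,
               minima = find_minima(sp),
               power_law = tryCatch(
                 unclass(fit_repulsive_power_law(sp))[c("exponent",
                                                        "prefactor",
                                                        "fit_range")],
                 error = function(e) NULL))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
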
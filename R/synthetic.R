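# Synthetic chains and fragment samples with known ground truth, so every
# pipeline stage can be validated end-to-end without external data:
#   - ideal Gaussian chains (the ideal-chain null of the Maxwell reference),
#   - compact confined chains with Rg ~ N^(1/3) (globularity-filter input),
#   - rod-like extended chains with Rg ~ N (planted filter outliers),
#   - end-to-end distance samples drawn from the Maxwell distribution
#     reweighted by a known injected potential U(R) (inversion ground truth).

#' Generate an ideal Gaussian chain
#'
#' CA-only trace whose successive displacements are independent isotropic 3D
#' Gaussian steps with per-component standard deviation `b / sqrt(3)`, so the
#' mean squared end-to-end distance between residues i and i+m is exactly
#' `b^2 * m`. Excluded volume is deliberately absent (this is the ideal-chain
#' null); `hard_core` adds a rejection radius for stress tests.
#'
#' @param N number of residues, >= 2.
#' @param b step (Kuhn) length, Angstrom; default 3.8, the typical
#'   consecutive-CA distance in proteins.
#' @param seed optional seed (local to this call).
#' @param aa residue types (recycled); default `"GLY"`.
#' @param hard_core optional minimal distance between consecutive step
#'   endpoints' predecessors, Angstrom; steps violating it are redrawn.
#' @param max_retry rejection cap per step.
#' @return an `fr_chain`.
#' @export
generate_gaussian_chain <- function(N, b = 3.8, seed = NULL, aa = "GLY",
                                    hard_core = NULL, max_retry = 1e4L) {
  stopifnot(N >= 2L, b > 0)
  with_seed(seed, {
    if (is.null(hard_core)) {
      steps <- matrix(stats::rnorm(3L * (N - 1L), sd = b / sqrt(3)),
                      ncol = 3L)
      ca <- rbind(0, apply(steps, 2L, cumsum))
    } else {
      ca <- matrix(0, N, 3L)
      for (i in 2:N) {
        for (tries in seq_len(max_retry)) {
          p <- ca[i - 1L, ] + stats::rnorm(3L, sd = b / sqrt(3))
          d2min <- min(rowSums(sweep(ca[seq_len(i - 1L), , drop = FALSE],
                                     2L, p)^2))
          if (d2min >= hard_core^2) break
          if (tries == max_retry)
            stop("hard-core rejection stalled at residue ", i)
        }
        ca[i, ] <- p
      }
    }
    new_chain(ca, aa = aa, id = "S")
  })
}

#' Generate an ensemble of Gaussian chains
#'
#' Chain i is generated with seed `seed + i - 1`, giving deterministic yet
#' independent streams.
#'
#' @param n_chains number of chains.
#' @param N residues per chain.
#' @param b step length, Angstrom.
#' @param seed base seed.
#' @param aa residue types passed through to each chain.
#' @return list of `fr_chain`.
#' @export
generate_gaussian_ensemble <- function(n_chains, N, b = 3.8, seed = 1L,
                                       aa = "GLY") {
  lapply(seq_len(n_chains), function(i)
    generate_gaussian_chain(N, b = b, seed = seed + i - 1L, aa = aa))
}

#' Generate a compact confined chain
#'
#' Gaussian-step chain whose steps are redrawn (rejection) whenever they
#' would leave a sphere of radius `radius_factor * N^(1/3)` centred at the
#' origin. Across an ensemble the radius of gyration scales as `N^(1/3)`,
#' emulating globular proteins for the globularity filter.
#'
#' @param N number of residues.
#' @param radius_factor sphere radius prefactor (Angstrom per N^(1/3));
#'   default 2, chosen so the finite walk equilibrates inside its sphere
#'   across ensemble sizes (larger spheres leave an N^(-1/3) transient that
#'   distorts the apparent scaling exponent at small N).
#' @param b step length, Angstrom.
#' @param seed optional seed (local to this call).
#' @param aa residue types.
#' @param max_retry rejection cap per step; exceeding it is a generation
#'   error.
#' @return an `fr_chain` whose coordinates all lie within the sphere.
#' @export
generate_confined_globule <- function(N, radius_factor = 2, b = 3.8,
                                      seed = NULL, aa = "GLY",
                                      max_retry = 1e4L) {
  stopifnot(N >= 2L, radius_factor > 0, b > 0)
  radius <- radius_factor * N^(1 / 3)
  if (radius <= b)
    stop("confinement sphere smaller than one step; increase radius_factor")
  with_seed(seed, {
    ca <- matrix(0, N, 3L)
    for (i in 2:N) {
      ok <- FALSE
      for (tries in seq_len(max_retry)) {
        p <- ca[i - 1L, ] + stats::rnorm(3L, sd = b / sqrt(3))
        if (sum(p^2) <= radius^2) { ok <- TRUE; break }
      }
      if (!ok) stop("confined-step rejection stalled at residue ", i)
      ca[i, ] <- p
    }
    ch <- new_chain(ca, aa = aa, id = "G")
    ch$radius <- radius
    ch
  })
}

#' Generate a rod-like extended chain
#'
#' Residues advance along one axis with small transverse jitter, so
#' `Rg ~ N` (prefactor `rise / sqrt(12)`). Used to plant non-globular
#' outliers for the globularity filter.
#'
#' @param N number of residues.
#' @param rise per-residue advance, Angstrom (default 3.5).
#' @param jitter transverse Gaussian jitter sd, Angstrom.
#' @param seed optional seed.
#' @param aa residue types.
#' @return an `fr_chain`.
#' @export
generate_extended_chain <- function(N, rise = 3.5, jitter = 0.5, seed = NULL,
                                    aa = "GLY") {
  stopifnot(N >= 2L, rise > 0)
  with_seed(seed, {
    ca <- cbind(rise * (seq_len(N) - 1L),
                stats::rnorm(N, sd = jitter),
                stats::rnorm(N, sd = jitter))
    new_chain(ca, aa = aa, id = "E")
  })
}

#' Sample end-to-end distances from a reweighted Maxwell density
#'
#' Draws n distances by rejection sampling from the density proportional to
#' `M_m(R, b) * exp(-U(R))`, the exact form the Boltzmann-inversion stage is
#' meant to recover: feeding the returned sample through the KDE and
#' inversion machinery should give back U up to an additive constant.
#' `U` must be bounded below on (0, Inf); the acceptance envelope is the
#' Maxwell proposal scaled by `exp(-min U)` (minimum taken on a fine grid).
#'
#' @param m sequence separation.
#' @param b Kuhn length of the underlying Maxwell distribution, Angstrom.
#' @param U vectorized function of distance returning the injected potential
#'   in kB*T; may return `Inf` (hard exclusion) but not `-Inf`.
#' @param n sample size.
#' @param seed optional seed (local to this call).
#' @param min_acceptance abort below this acceptance rate with a hint to use
#'   a better envelope.
#' @return a `fragment_set` at level `"CA"` (no terminal types).
#' @export
sample_reweighted_maxwell <- function(m, b, U, n, seed = NULL,
                                      min_acceptance = 1e-4) {
  stopifnot(m >= 1, b > 0, n >= 1)
  rmax <- b * sqrt(m) * 6
  ugrid <- U(seq(1e-3, rmax, length.out = 4096L))
  umin <- min(ugrid[is.finite(ugrid)])
  if (!is.finite(umin)) stop("injected potential U is unbounded below")
  with_seed(seed, {
    out <- numeric(0)
    proposed <- 0L
    while (length(out) < n) {
      batch <- max(2L * (n - length(out)), 1000L)
      r <- sample_maxwell(batch, b, m)
      acc_p <- exp(-(U(r) - umin))
      acc_p[!is.finite(acc_p)] <- 0
      keep <- stats::runif(batch) < acc_p
      out <- c(out, r[keep])
      proposed <- proposed + batch
      if (proposed >= 1e4L && length(out) / proposed < min_acceptance)
        stop("rejection acceptance rate below ", min_acceptance,
             "; provide a tighter envelope or rescale U")
    }
    new_fragment_set(m, "CA", out[seq_len(n)])
  })
}

#' Write a chain (or chains) as a PDB file
#'
#' Standard fixed-width ATOM records; CA-only traces are written as CA atoms
#' of their residue types (default GLY). Coordinates survive a round trip
#' through [load_structure] to the format's 1e-3 Angstrom precision.
#'
#' @param chain an `fr_chain`, `fr_structure`, or list of chains.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pdb <- function(chain, path) {
  chains <- as_chain_list(chain)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing"))
  on.exit(close(con))
  serial <- 0L
  chain_ids <- strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1L]]
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    cid <- chain_ids[(ci - 1L) %% 26L + 1L]
    for (i in seq_len(ch$N)) {
      res <- chain_residue(ch, i)
      for (a in seq_along(res$name)) {
        serial <- serial + 1L
        nm <- res$name[a]
        # PDB atom-name column convention: 1-char element symbols start in
        # column 14
        nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm)
                  else sprintf("%-4s", nm)
        writeLines(sprintf(
          "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm_fmt, res$aa, cid, ch$resno[i] %% 10000L,
          res$xyz[a, 1L], res$xyz[a, 2L], res$xyz[a, 3L], 1, 0,
          res$element[a]), con)
      }
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a JSON manifest of generator parameters
#'
#' @param params named list of generator parameters (kind, N, b, seed, ...).
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
write_manifest <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
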
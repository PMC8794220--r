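# helper: an empirical_density equal to an analytic curve (bypasses sampling)
analytic_density <- function(values, grid = default_distance_grid(),
                             m = 70L, n = 1e6L, w = 0.5, level = "CA") {
  structure(list(grid = grid, density = values, w = w, m = as.integer(m),
                 n = n, level = level),
            class = "empirical_density")
}

ref_fit <- function(b = 3.67, m = 70L, n = 1e6L, level = "CA") {
  structure(list(m = as.integer(m), b = b, sigma_b = b / sqrt(6 * n), n = n,
                 level = level),
            class = "maxwell_fit")
}

test_that("inverting the reference against itself gives a zero potential", {
  grid <- default_distance_grid()
  E <- analytic_density(maxwell_pdf(grid, 3.67, 70))
  V <- boltzmann_inversion(E, ref_fit())
  expect_gt(sum(V$defined), 200L)
  expect_equal(max(abs(V$V[V$defined])), 0, tolerance = 1e-12)
  # outside the support the curve is NA, never infinite
  expect_true(all(is.na(V$V[!V$defined])))
})

test_that("inversion refuses mismatched separations and undersupported points", {
  grid <- default_distance_grid()
  E <- analytic_density(maxwell_pdf(grid, 3.67, 70), m = 70L, n = 1000L)
  expect_error(boltzmann_inversion(E, ref_fit(m = 80L)), "mismatch")
  V <- boltzmann_inversion(E, ref_fit(m = 70L, n = 1000L))
  # with n = 1000 the 5-count support threshold bites: low-density wings NA
  expect_true(any(!V$defined & grid > 0 & grid < 10))
})

test_that("averaging uses the pointwise mean and population spread", {
  grid <- seq(0, 10, 0.1)
  mk <- function(v, m) structure(list(grid = grid, V = v,
                                      defined = !is.na(v), m = m,
                                      level = "CA", b = 3.67, w = 1,
                                      n = 1000L),
                                 class = "potential_curve")
  same <- lapply(70:72, function(m) mk(rep(0.3, length(grid)), m))
  sp <- average_potential(same)
  expect_equal(sp$average, rep(0.3, length(grid)))
  expect_equal(sp$spread, rep(0, length(grid)))

  two <- list(mk(rep(1, length(grid)), 70L), mk(rep(-1, length(grid)), 71L))
  sp2 <- average_potential(two)
  expect_equal(sp2$average, rep(0, length(grid)))
  expect_equal(sp2$spread, rep(1, length(grid)))  # population sd, n = 2

  # by default a point undefined in any curve is undefined in the average
  v_hole <- rep(1, length(grid)); v_hole[5] <- NA
  sp3 <- average_potential(list(mk(v_hole, 70L),
                                mk(rep(1, length(grid)), 71L)))
  expect_true(is.na(sp3$average[5]))
  sp4 <- average_potential(list(mk(v_hole, 70L),
                                mk(rep(1, length(grid)), 71L)),
                           min_fraction = 0.5)
  expect_equal(sp4$average[5], 1)
})

test_that("minima are found at parabola vertices and absent on monotone curves", {
  grid <- seq(0, 10, 0.1)
  parab <- list(grid = grid, values = (grid - 5)^2)
  mn <- find_minima(parab)
  expect_equal(nrow(mn), 1L)
  expect_equal(mn$position, 5.0, tolerance = 1e-9)
  expect_equal(mn$value, 0.0, tolerance = 1e-9)

  mono <- list(grid = grid, values = exp(-grid))
  expect_equal(nrow(find_minima(mono)), 0L)

  dwell <- list(grid = grid,
                values = -1.5 * dnorm(grid, 3, 0.6) - 0.8 * dnorm(grid, 7, 0.6))
  mn2 <- find_minima(dwell)
  expect_equal(nrow(mn2), 2L)
  expect_equal(mn2$position, c(3, 7), tolerance = 0.1)
})

test_that("exact power laws are recovered to numerical precision", {
  grid <- seq(0.5, 10, 0.1)
  pf <- fit_repulsive_power_law(list(grid = grid, values = grid^-6),
                                fit_range = c(0.5, 5))
  expect_equal(pf$exponent, -6.0, tolerance = 1e-9)
  pf2 <- fit_repulsive_power_law(list(grid = grid, values = 2 * grid^-3),
                                 fit_range = c(0.5, 5))
  expect_equal(pf2$exponent, -3.0, tolerance = 1e-9)
  expect_equal(pf2$prefactor, 2.0, tolerance = 1e-9)
  expect_error(
    fit_repulsive_power_law(list(grid = grid, values = 1 - grid / 5),
                            fit_range = c(0.5, 9)), "V <= 0")
})

test_that("whole-chain scores equal a brute-force double loop", {
  grid <- default_distance_grid()
  set.seed(61)
  ms <- 5:12
  curves <- lapply(ms, function(m) {
    v <- 0.5 * sin(grid / (1 + m / 10)) * exp(-grid / 15)
    v[grid < 2 | grid > 25] <- NA  # undefined support edges exercise clamping
    structure(list(grid = grid, V = v, defined = !is.na(v), m = m,
                   level = "CA", b = 3.8, w = 1, n = 1000L),
              class = "potential_curve")
  })
  sp <- average_potential(curves, kind = "broad_30_90", min_fraction = 0)
  ch <- generate_gaussian_chain(200, seed = 303)
  sc <- score_structure(ch, sp, level = "CA")

  # independent summation: plain double loop with boundary clamping
  brute <- 0
  for (i in 1:199) for (j in (i + 1):200) {
    m <- j - i
    if (!(m %in% ms)) next
    r <- sqrt(sum((ch$ca[i, ] - ch$ca[j, ])^2))
    v <- sp$per_m[as.character(m), ]
    def <- which(!is.na(v))
    rc <- min(max(r, grid[def[1]]), grid[def[length(def)]])
    brute <- brute + approx(grid[def], v[def], xout = rc)$y
  }
  expect_equal(sc$v_tot, brute, tolerance = 1e-10)

  zero <- average_potential(lapply(curves, function(cv) {
    cv$V[] <- 0; cv$defined[] <- TRUE; cv
  }), kind = "broad_30_90")
  expect_equal(score_structure(ch, zero)$v_tot, 0)
})

test_that("a three-residue chain scores as the hand-summed single term", {
  grid <- seq(0, 10, 0.1)
  v <- rep(0.25, length(grid))
  cv <- structure(list(grid = grid, V = v, defined = rep(TRUE, length(grid)),
                       m = 2L, level = "CA", b = 3.8, w = 1, n = 10L),
                  class = "potential_curve")
  sp <- average_potential(list(cv), kind = "broad_30_90")
  ch <- new_chain(rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)))
  sc <- score_structure(ch, sp)
  expect_equal(sc$v_tot, 0.25)            # only the (1,3) pair is supported
  expect_equal(sc$n_pairs_skipped, 2L)    # (1,2) and (2,3) at m = 1
})

test_that("null injected potential round-trips through sampling, KDE and inversion", {
  m <- 70L; b <- 3.67
  fs <- sample_reweighted_maxwell(m, b, function(R) rep(0, length(R)), 3e4,
                                  seed = 93)
  ref <- fit_kuhn_length(fs)
  w <- as.numeric(cross_validate_bandwidth(fs, seed = 94))
  V <- boltzmann_inversion(empirical_density(fs, w = w), ref)
  band <- sqrt(qchisq(c(0.025, 0.975), 3) / 3) * b * sqrt(m)
  sel <- V$defined & V$grid >= band[1] & V$grid <= band[2]
  expect_gt(sum(sel), 50L)
  expect_lt(max(abs(V$V[sel])), 0.1)
})

test_that("sequence-restricted sets reproduce the unrestricted potential when the filter is trivial", {
  m_vals <- 30:34
  fsets <- lapply(m_vals, function(m) {
    d <- sample_maxwell(4000, 3.67, m, seed = 700 + m)
    floryref:::new_fragment_set(m, "CA", d,
                                matrix("GLY", length(d), 2L))
  })
  names(fsets) <- m_vals
  bm <- fit_bandwidth_scaling(n = c(1000, 4000, 16000),
                              w = 1.0 * c(1000, 4000, 16000)^(-0.2))
  sp_pair <- derive_sequence_dependent(fsets, "GLY", "GLY", bw_model = bm,
                                       m_range = c(30, 34))
  # unrestricted derivation with the same inputs
  curves <- lapply(fsets, function(fs) {
    ref <- fit_kuhn_length(fs)
    w <- predict_bandwidth(bm, fs$n)
    boltzmann_inversion(empirical_density(fs, w = w), ref)
  })
  sp_all <- average_potential(curves, kind = "broad_30_90")
  expect_equal(sp_pair$average, sp_all$average, tolerance = 1e-12)
  expect_equal(sp_pair$pair, c("GLY", "GLY"))
})

test_that("type-dependent injected wells separate the recovered pair potentials", {
  m_vals <- c(30L, 35L, 40L)
  U_attr <- function(R) -1.0 * exp(-(R - 8)^2 / (2 * 1.5^2))  # attractive
  U_rep <- function(R) 1.0 * exp(-(R - 8)^2 / (2 * 1.5^2))    # repulsive
  mk_sets <- function() {
    fsets <- lapply(m_vals, function(m) {
      da <- sample_reweighted_maxwell(m, 3.67, U_attr, 10000,
                                      seed = 800 + m)$distances
      dr <- sample_reweighted_maxwell(m, 3.67, U_rep, 10000,
                                      seed = 900 + m)$distances
      floryref:::new_fragment_set(
        m, "CA", c(da, dr),
        rbind(matrix("ALA", length(da), 2L), matrix("GLU", length(dr), 2L)))
    })
    names(fsets) <- m_vals
    fsets
  }
  fsets <- mk_sets()
  bm <- fit_bandwidth_scaling(n = c(1000, 4000, 16000),
                              w = 1.0 * c(1000, 4000, 16000)^(-0.2))
  sp_a <- derive_sequence_dependent(fsets, "ALA", "ALA", bw_model = bm,
                                    m_range = range(m_vals))
  sp_r <- derive_sequence_dependent(fsets, "GLU", "GLU", bw_model = bm,
                                    m_range = range(m_vals))
  sel <- which(!is.na(sp_a$average) & !is.na(sp_r$average) &
               abs(sp_a$grid - 8) <= 1)
  # gauge-fix each curve by its mean far from the well before comparing
  far_a <- mean(sp_a$average[!is.na(sp_a$average) & sp_a$grid > 15])
  far_r <- mean(sp_r$average[!is.na(sp_r$average) & sp_r$grid > 15])
  expect_lt(mean(sp_a$average[sel]) - far_a, -0.4)
  expect_gt(mean(sp_r$average[sel]) - far_r, 0.4)

  expect_error(derive_sequence_dependent(fsets, "TRP", "TRP", bw_model = bm),
               "insufficient")
})

test_that("potentials export as TSV with a JSON sidecar", {
  grid <- default_distance_grid()
  curves <- lapply(70:72, function(m) {
    E <- analytic_density(maxwell_pdf(grid, 3.67, m) *
                            exp(-(-1) * dnorm(grid, 6, 1)), m = m)
    boltzmann_inversion(E, ref_fit(m = m))
  })
  sp <- average_potential(curves)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_potential(sp, tsv)
  lines <- readLines(tsv)
  expect_match(lines[1L], "^# level=CA kind=flory_70_90")
  tab <- read.delim(tsv, skip = 1L)
  expect_named(tab, c("R", "V_mean", "V_sd", "n_curves"))
  meta <- jsonlite::read_json(paste0(tsv, ".json"))
  expect_equal(meta$kind, "flory_70_90")
})
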
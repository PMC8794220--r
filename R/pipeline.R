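# End-to-end derivation: structures -> globularity pruning -> fragment
# statistics -> Kuhn-length fits -> CV bandwidths -> KDE densities ->
# Boltzmann inversion -> averaged potentials and their analysis.

#' Build a pipeline configuration
#'
#' Collects every tunable of the derivation in one serializable object.
#' Defaults mirror the reference workflow: fragments collected for
#' 30 <= m <= 90 (subject to the per-chain buriedness bound m < N^(2/3)),
#' Kuhn plateau and Flory-average over 70 <= m <= 90, broad average over
#' 30 <= m <= 90, 3-sigma globularity pruning, bandwidth cross-validation at
#' m in {42, 48, 60, 64, 66, 72, 78, 84, 92} with 5 folds.
#'
#' @param input_dir directory of structure files (.pdb/.ent/.cif/.mmcif), or
#'   `NULL` when `chains` are passed to [run_pipeline] directly.
#' @param output_dir run directory for all artifacts.
#' @param levels coarse-graining levels to run.
#' @param m_collect,m_plateau,m_broad inclusive separation ranges.
#' @param k_sigma globularity discard threshold.
#' @param cv_m separations at which bandwidths are cross-validated.
#' @param n_folds CV folds.
#' @param seed master seed for fold assignment and subsampling.
#' @param grid shared distance grid.
#' @param tangent_m_max largest separation in the tangent-correlation report.
#' @param seq_pairs optional list of 2-vectors of residue codes for the
#'   sequence-dependent pass.
#' @param min_pair_count minimum restricted-fragment count per separation in
#'   the sequence-dependent pass.
#' @param min_support_count Boltzmann-inversion support threshold.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = tempfile("flory_run_"),
                            levels = "CA",
                            m_collect = c(30L, 90L),
                            m_plateau = c(70L, 90L),
                            m_broad = c(30L, 90L),
                            k_sigma = 3,
                            cv_m = c(42L, 48L, 60L, 64L, 66L, 72L, 78L, 84L, 92L),
                            n_folds = 5L, seed = 1L,
                            grid = default_distance_grid(),
                            tangent_m_max = 40L,
                            seq_pairs = NULL, min_pair_count = 50L,
                            min_support_count = 5) {
  levels <- vapply(levels, match_level, "")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 levels = unname(levels), m_collect = m_collect,
                 m_plateau = m_plateau, m_broad = m_broad,
                 k_sigma = k_sigma, cv_m = cv_m, n_folds = n_folds,
                 seed = seed, grid = grid, tangent_m_max = tangent_m_max,
                 seq_pairs = seq_pairs, min_pair_count = min_pair_count,
                 min_support_count = min_support_count),
            class = "pipeline_config")
}

load_structure_dir <- function(input_dir) {
  files <- list.files(input_dir, pattern = "\\.(pdb|ent|cif|mmcif)$",
                      full.names = TRUE, ignore.case = TRUE)
  if (length(files) == 0L)
    stop("no structure files (.pdb/.ent/.cif/.mmcif) in '", input_dir, "'")
  lapply(files, load_structure)
}

#' Run the full potential-derivation pipeline
#'
#' Stages, in order: load structures; per-chain radius of gyration and
#' globularity pruning; tangent-correlation report; per level: buried
#' fragment collection, per-m Kuhn-length fits, plateau and thermal
#' exponent, cross-validated bandwidths and the w = a n^s model, per-m KDE
#' densities and Boltzmann inversions, Flory-regime average V* and broad
#' average, minima and short-range power-law fit; optional
#' sequence-dependent pass. All intermediates are written under the run
#' directory as TSV/JSON; a stage failure aborts with the stage name,
#' leaving completed intermediates on disk.
#'
#' @param config a `pipeline_config`.
#' @param chains optional pre-loaded ensemble (chain/structure list),
#'   bypassing `input_dir`.
#' @return summary list (also written as `summary.json`): per level the
#'   plateau Kuhn length, thermal exponent, bandwidth model, minima and
#'   power-law fit, plus pruning/collection counts.
#' @export
run_pipeline <- function(config, chains = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  jsonlite::write_json(config[setdiff(names(config), "grid")],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  chains <- stage("load", {
    if (is.null(chains)) {
      if (is.null(config$input_dir)) stop("no input_dir and no chains given")
      as_chain_list(load_structure_dir(config$input_dir))
    } else as_chain_list(chains)
  })

  glob <- stage("globularity_filter", {
    pts <- data.frame(
      id = vapply(seq_along(chains), function(i)
        paste0(chains[[i]]$id, "#", i), ""),
      N = vapply(chains, function(ch) ch$N, 0L),
      Rg = vapply(chains, radius_of_gyration, 0))
    g <- fit_globularity(pts, k_sigma = config$k_sigma)
    write_globularity_report(g, file.path(out_dir, "globularity.tsv"))
    g
  })
  retained <- chains[glob$table$retained]
  if (length(retained) == 0L)
    stop("pipeline stage 'globularity_filter' failed: no chain retained")

  tang <- stage("tangent_correlation", {
    tc <- tangent_correlation(retained, m_max = config$tangent_m_max)
    utils::write.table(tc, file.path(out_dir, "tangent_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tc
  })

  summary <- list(
    n_chains = length(chains),
    n_retained = length(retained),
    n_discarded = length(glob$discarded_ids),
    globularity_a = glob$a,
    levels = list())

  for (level in config$levels) {
    fsets <- stage(paste0("fragments_", level), {
      fs <- collect_distances(retained, m_range = config$m_collect,
                              level = level)
      write_fragments(fs, file.path(out_dir,
                                    sprintf("fragments_%s.tsv", level)))
      fs
    })
    nonempty <- vapply(fsets, function(f) f$n, 0L) > 0L

    fits <- stage(paste0("kuhn_fits_", level), {
      f <- lapply(fsets[nonempty], fit_kuhn_length)
      write_kuhn_fits(f, file.path(out_dir, sprintf("fits_%s.tsv", level)))
      f
    })

    plateau <- stage(paste0("plateau_", level),
                     plateau_kuhn_length(fits, config$m_plateau))

    scaling <- stage(paste0("thermal_exponent_", level), {
      mr <- vapply(fsets[nonempty], function(f) mean(f$distances), 0)
      names(mr) <- vapply(fsets[nonempty], function(f) f$m, 0L)
      scaling_exponent(mr, config$m_plateau)
    })

    bw <- stage(paste0("bandwidths_", level), {
      eligible <- as.integer(names(fsets)[nonempty])
      eligible <- eligible[vapply(as.character(eligible), function(k)
        fsets[[k]]$n >= 2L * config$n_folds, TRUE)]
      cvm <- intersect(config$cv_m, eligible)
      if (length(cvm) < 2L) {
        # configured CV list lies outside the collected range: fall back to
        # an evenly spread subset of the available separations
        cvm <- unique(eligible[round(seq(1L, length(eligible),
                                         length.out = min(5L,
                                                          length(eligible))))])
      }
      if (length(cvm) < 2L)
        stop("fewer than 2 separations eligible for bandwidth CV")
      wcv <- vapply(as.character(cvm), function(k)
        as.numeric(cross_validate_bandwidth(fsets[[k]],
                                            n_folds = config$n_folds,
                                            seed = config$seed)), 0)
      ns <- vapply(as.character(cvm), function(k) fsets[[k]]$n, 0L)
      utils::write.table(data.frame(m = cvm, n = ns, w_cv = wcv),
                         file.path(out_dir,
                                   sprintf("bandwidths_%s.tsv", level)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fit_bandwidth_scaling(n = ns, w = wcv)
    })

    curves <- stage(paste0("potentials_", level), {
      dens_tab <- list()
      cv <- list()
      for (k in which(nonempty)) {
        fs <- fsets[[k]]
        w <- predict_bandwidth(bw, fs$n)
        E <- empirical_density(fs, w = w, grid = config$grid)
        dens_tab[[length(dens_tab) + 1L]] <-
          data.frame(m = fs$m, R = E$grid, density = E$density)
        cv[[length(cv) + 1L]] <-
          boltzmann_inversion(E, fits[[match(k, which(nonempty))]],
                              min_count = config$min_support_count)
      }
      utils::write.table(do.call(rbind, dens_tab),
                         file.path(out_dir,
                                   sprintf("densities_%s.tsv", level)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cv
    })

    v_star <- stage(paste0("average_flory_", level), {
      sp <- average_potential(curves, m_range = config$m_plateau,
                              kind = "flory_70_90")
      write_potential(sp, file.path(out_dir,
                                    sprintf("potential_%s_flory.tsv", level)))
      sp
    })
    v_broad <- stage(paste0("average_broad_", level), {
      sp <- average_potential(curves, m_range = config$m_broad,
                              kind = "broad_30_90")
      write_potential(sp, file.path(out_dir,
                                    sprintf("potential_%s_broad.tsv", level)))
      sp
    })

    minima <- find_minima(v_star, significant_only = TRUE)
    power <- tryCatch(fit_repulsive_power_law(v_broad),
                      error = function(e) NULL)

    seqdep <- NULL
    if (!is.null(config$seq_pairs)) {
      seqdep <- stage(paste0("seqdep_", level), {
        lapply(config$seq_pairs, function(pr) {
          sp <- tryCatch(
            derive_sequence_dependent(fsets, pr[1L], pr[2L], bw_model = bw,
                                      m_range = config$m_broad,
                                      min_count_per_m = config$min_pair_count,
                                      grid = config$grid,
                                      min_support_count = config$min_support_count,
                                      seed = config$seed),
            error = function(e) e)
          if (!inherits(sp, "error"))
            write_potential(sp, file.path(out_dir,
              sprintf("potential_%s_%s-%s.tsv", level, pr[1L], pr[2L])))
          sp
        })
      })
    }

    summary$levels[[level]] <- list(
      n_fragments = stats::setNames(vapply(fsets, function(f) f$n, 0L),
                                    names(fsets)),
      n_skipped = sum(vapply(fsets, function(f) f$skipped, 0L)),
      b_star = plateau$b_star, sigma_b_star = plateau$sigma_b_star,
      b_by_m = plateau$b_by_m,
      nu = scaling$nu,
      bandwidth_a = bw$a_bw, bandwidth_s = bw$s_bw,
      minima = minima,
      power_law = if (!is.null(power))
        unclass(power)[c("exponent", "prefactor", "fit_range")] else NULL,
      seqdep_pairs = if (!is.null(seqdep))
        vapply(config$seq_pairs, paste, "", collapse = "-") else NULL)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  summary$tangent <- tang
  summary$globularity <- glob
  invisible(summary)
}
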
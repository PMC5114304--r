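#' Experiment configuration
#'
#' Builds the full configuration for a phantom reliability experiment,
#' merging user overrides into the defaults. The default design matches
#' the emulated study: 10 subjects, 3 of them with one rescan, icosphere
#' resolution 4 (2562 vertices, mean edge ~0.75 mm at radius 10 mm),
#' depth averaging over 20--80%, exclusion at T2* < 0.024 s, curvature
#' residualization of T1w and R1 only, 1 mm pre-smoothing for the border
#' analyses, AUC coverage thresholds 60--90% and contours at 75/80/85%.
#'
#' @param mesh List: `kind`, `resolution`, `radius`, `spacing`.
#' @param design List: `n_subjects`, `n_rescans`.
#' @param population Overrides for [population_params()].
#' @param acquisition Overrides for [acquisition_spec()]; the `transform`
#'   element holds overrides for [weighted_transform_params()].
#' @param analysis List: `depth_lo`, `depth_hi`, `exclusion_threshold`,
#'   `smooth_fwhm_mm`, `residualize` (parameter names), `fwhm_method`,
#'   `coverage_pcts`, `contour_pcts`, `jaccard_pct`, `cnr_ref_mode`.
#' @param seed Master seed; all subject/session/reference seeds derive
#'   from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(mesh = list(), design = list(),
                              population = list(), acquisition = list(),
                              analysis = list(), seed = 1L) {
  cfg <- list(
    mesh = utils::modifyList(
      list(kind = "icosphere", resolution = 4L, radius = 10, spacing = 1),
      mesh),
    design = utils::modifyList(
      list(n_subjects = 10L, n_rescans = 3L), design),
    population = population,
    acquisition = acquisition,
    analysis = utils::modifyList(
      list(depth_lo = 0.2, depth_hi = 0.8, exclusion_threshold = 0.024,
           smooth_fwhm_mm = 1.0, residualize = c("R1", "T1w"),
           fwhm_method = "kde", coverage_pcts = seq(60, 90, by = 5),
           contour_pcts = c(75, 80, 85), jaccard_pct = 80,
           cnr_ref_mode = "random_vertex"),
      analysis),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

validate_config <- function(cfg) {
  a <- cfg$analysis
  d <- cfg$design
  if (d$n_subjects < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (d$n_rescans < 1L || d$n_rescans > d$n_subjects) {
    stop("`n_rescans` must lie in [1, n_subjects]", call. = FALSE)
  }
  if (a$depth_lo > a$depth_hi) stop("depth_lo > depth_hi", call. = FALSE)
  if (a$exclusion_threshold < 0) {
    stop("exclusion threshold must be non-negative", call. = FALSE)
  }
  if (!all(a$residualize %in% parameter_names())) {
    stop("unknown parameter in `residualize`", call. = FALSE)
  }
  if (!a$fwhm_method %in% c("kde", "histogram")) {
    stop("`fwhm_method` must be kde or histogram", call. = FALSE)
  }
  if (any(a$coverage_pcts < 0 | a$coverage_pcts > 100)) {
    stop("coverage pcts must lie in [0, 100]", call. = FALSE)
  }
  invisible(cfg)
}

# stable content hash of the configuration (polynomial over the YAML text)
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass_deep(config))
  h <- 0
  for (x in utf8ToInt(txt)) h <- (h * 131 + x) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Run the full phantom reliability experiment
#'
#' Generates the cohort (N subjects, a subset with one rescan each),
#' computes all six parameter maps per session, applies the T2* exclusion
#' mask, curvature-residualizes the configured parameters, and derives
#' every group-level result: inter-/intra-subject FWHM-normalized COV
#' tables, parcellability variation, CNR per unit scan time, depth-resolved
#' correlations, AUC coverage profiles, threshold contours, a pairwise
#' Jaccard matrix between parameter parcellations, and surface gradient
#' maps. Fully reproducible from `config$seed`.
#'
#' @param config An [experiment_config()].
#' @param verbose Emit stage messages.
#' @return A `report_bundle`: tables (`cov_inter`, `cov_intra`, `pv`,
#'   `cnr`, `depth_correlation`, `coverage`, `jaccard`), per-vertex maps
#'   (`group_maps`, `cov_maps`, `pv_maps`, `gradient_maps`, `exclude`),
#'   `contours`, `summaries` (per-parameter [distribution_summary()]),
#'   the `mesh`, `atlas`, `config` and a run `manifest`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  a <- config$analysis
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  seed <- config$seed
  params <- parameter_names()

  say("stage mesh: %s resolution %d", config$mesh$kind,
      config$mesh$resolution)
  mesh <- build_mesh(config$mesh$kind, config$mesh$resolution,
                     radius = config$mesh$radius,
                     spacing = config$mesh$spacing)
  atlas <- build_atlas(mesh)
  pop <- do.call(population_params, config$population)
  acq_over <- config$acquisition
  if (!is.null(acq_over$transform)) {
    acq_over$transform <- do.call(weighted_transform_params,
                                  acq_over$transform)
  }
  acq <- do.call(acquisition_spec, acq_over)

  n_sub <- config$design$n_subjects
  n_re <- config$design$n_rescans
  say("stage simulate: %d subjects, %d rescans, seed %d", n_sub, n_re, seed)
  sessions <- vector("list", n_sub)
  rescans <- vector("list", n_re)
  for (s in seq_len(n_sub)) {
    gt <- sample_ground_truth(mesh, atlas, pop, derive_seed(seed, s))
    sid <- sprintf("S%02d", s)
    sessions[[s]] <- simulate_session(gt, acq, derive_seed(seed, s, 1),
                                      subject_id = sid, session_id = 1L)
    if (s <= n_re) {
      rescans[[s]] <- simulate_session(gt, acq, derive_seed(seed, s, 2),
                                       subject_id = sid, session_id = 2L)
    }
  }

  davg <- function(sess, p) {
    depth_average(sess$maps[[p]]$depths, a$depth_lo, a$depth_hi)
  }

  say("stage exclude: T2* < %.3f s across-subject average",
      a$exclusion_threshold)
  t2s_group <- rowMeans(vapply(sessions, davg, numeric(nrow(mesh$vertices)),
                               p = "T2s"))
  exclude <- exclusion_mask(t2s_group, a$exclusion_threshold)
  say("  %d of %d vertices excluded", sum(exclude), length(exclude))

  mask_na <- function(v) {
    v[exclude] <- NA_real_
    v
  }
  # depth-averaged maps per parameter: subjects (session 1) and rescans,
  # curvature-residualized where configured, exclusion applied
  subj_maps <- list()
  rescan_maps <- list()
  for (p in params) {
    prep <- function(sess) {
      v <- mask_na(davg(sess, p))
      if (p %in% a$residualize) {
        v <- curvature_residualize(v, mesh$curvature)
      }
      v
    }
    subj_maps[[p]] <- vapply(sessions, prep, numeric(nrow(mesh$vertices)))
    rescan_maps[[p]] <- lapply(seq_len(n_re), function(s) {
      cbind(prep(sessions[[s]]), prep(rescans[[s]]))
    })
  }
  group_maps <- lapply(subj_maps, rowMeans)

  say("stage metrics: distribution summaries + COV/PV/CNR")
  summaries <- lapply(group_maps, distribution_summary,
                      method = a$fwhm_method)
  rois <- atlas$table$name[!atlas$table$background]

  cov_maps <- list()
  pv_maps <- list()
  roi_rows <- function(map, metric, p) {
    do.call(rbind, lapply(rois, function(r) {
      st <- roi_stats(map, atlas, r)
      data.frame(parameter = p, roi = r, metric = metric, mean = st$mean,
                 se = st$se, n = st$n, stringsAsFactors = FALSE)
    }))
  }
  cov_inter <- cov_intra <- pv_tab <- cnr_tab <- NULL
  for (p in params) {
    ds <- summaries[[p]]
    ci <- cov_vertexwise(subj_maps[[p]], ds$fwhm_rescaled, "inter")
    ca <- cov_vertexwise(rescan_maps[[p]], ds$fwhm_rescaled, "intra")
    pv <- pv_vertexwise(scan_rescan_sd(rescan_maps[[p]]), ds$fwhm_raw)
    cov_maps[[p]] <- list(inter = ci$cov, intra = ca$cov)
    pv_maps[[p]] <- pv
    cov_inter <- rbind(cov_inter, roi_rows(ci$cov, "cov_inter", p))
    cov_intra <- rbind(cov_intra, roi_rows(ca$cov, "cov_intra", p))
    pv_tab <- rbind(pv_tab, roi_rows(pv, "pv", p))
    cnr_tab <- rbind(cnr_tab, do.call(rbind, lapply(rois, function(r) {
      cn <- cnr_per_time(group_maps[[p]], atlas, r,
                         minutes = scan_minutes_for(p, acq),
                         ref_mode = a$cnr_ref_mode,
                         seed = derive_seed(seed, match(p, params),
                                            match(r, rois), 7L))
      data.frame(parameter = p, roi = r, metric = "cnr_per_min",
                 mean = cn$mean, se = cn$se, n = cn$n,
                 stringsAsFactors = FALSE)
    })))
  }

  say("stage correlation: depth-resolved parameter pairs")
  group_depths <- lapply(params, function(p) {
    acc <- 0
    for (s in seq_len(n_sub)) acc <- acc + sessions[[s]]$maps[[p]]$depths
    acc / n_sub
  })
  names(group_depths) <- params
  pairs <- list(c("R1", "T2s"), c("T1w", "T2sw"), c("R1/T2s", "T1w/T2sw"))
  depth_cor <- do.call(rbind, lapply(pairs, function(pr) {
    dc <- depthwise_correlation(group_depths[[pr[1]]], group_depths[[pr[2]]],
                                mask = exclude, lo = a$depth_lo,
                                hi = a$depth_hi)
    rbind(
      data.frame(pair = paste(pr, collapse = " vs "),
                 depth = depth_fractions(), r = dc$by_depth, n = dc$n),
      data.frame(pair = paste(pr, collapse = " vs "), depth = NA_real_,
                 r = dc$overall, n = dc$n)
    )
  }))

  say("stage parcellate: smoothing %.2f mm, AUC thresholds + gradients",
      a$smooth_fwhm_mm)
  # orient all parameters to increase with myelination for thresholding
  oriented <- group_maps
  oriented[["T2s"]] <- reciprocal_map(group_maps[["T2s"]])
  oriented[["T2sw"]] <- reciprocal_map(group_maps[["T2sw"]])
  smoothed <- lapply(oriented, function(v) {
    geodesic_smooth(mesh, v, a$smooth_fwhm_mm)
  })

  coverage <- do.call(rbind, lapply(params, function(p) {
    do.call(rbind, lapply(rois, function(r) {
      cp <- coverage_profile(smoothed[[p]], atlas, r, a$coverage_pcts)
      cbind(data.frame(parameter = p, roi = r, stringsAsFactors = FALSE),
            cp)
    }))
  }))

  contours <- lapply(params, function(p) {
    lapply(a$contour_pcts, function(pc) {
      thr <- auc_threshold(smoothed[[p]], pc)
      bc <- binarize_and_contour(mesh, smoothed[[p]], thr,
                                 source = list(parameter = p, pct = pc))
      list(pct = pc, threshold = thr, parcellation = bc$parcellation,
           contour = bc$contour)
    })
  })
  names(contours) <- params

  jp <- a$jaccard_pct
  masks <- lapply(params, function(p) {
    thr <- auc_threshold(smoothed[[p]], jp)
    binarize_and_contour(mesh, smoothed[[p]], thr)$parcellation
  })
  names(masks) <- params
  jac <- outer(seq_along(params), seq_along(params),
               Vectorize(function(i, j) jaccard(masks[[i]], masks[[j]])))
  dimnames(jac) <- list(params, params)

  gradient_maps <- lapply(smoothed, function(v) surface_gradient(mesh, v))

  manifest <- c(
    sprintf("config_hash: %s", config_hash(config)),
    sprintf("seed: %d", seed),
    sprintf("subjects: %d  rescans: %d", n_sub, n_re),
    sprintf("vertices: %d  excluded: %d", length(exclude), sum(exclude)),
    log_lines
  )
  say("done")

  structure(
    list(tables = list(cov_inter = cov_inter, cov_intra = cov_intra,
                       pv = pv_tab, cnr = cnr_tab,
                       depth_correlation = depth_cor, coverage = coverage),
         jaccard = jac, summaries = summaries,
         group_maps = group_maps, cov_maps = cov_maps, pv_maps = pv_maps,
         gradient_maps = gradient_maps, contours = contours,
         exclude = exclude, mesh = mesh, atlas = atlas, config = config,
         manifest = manifest),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n")
  cat(paste0("  ", x$manifest[1:4], collapse = "\n"), "\n")
  cat(sprintf("  tables: %s\n", paste(names(x$tables), collapse = ", ")))
  invisible(x)
}

#' Median metric per parameter from a report table
#'
#' Convenience accessor: the median across ROIs of a metric table's means,
#' per parameter (the quantity used to rank parameters).
#'
#' @param bundle A `report_bundle`.
#' @param table One of `"cov_inter"`, `"cov_intra"`, `"pv"`, `"cnr"`.
#' @return Named numeric vector over parameters.
#' @export
parameter_medians <- function(bundle, table = "cov_inter") {
  tab <- bundle$tables[[table]]
  if (is.null(tab)) stop("unknown table", call. = FALSE)
  out <- tapply(tab$mean, tab$parameter, stats::median)
  out[parameter_names()]
}

#' Write a report bundle to disk
#'
#' Emits the tidy CSV tables, the Jaccard matrix, contour edge lists, the
#' phantom surface and key per-vertex overlays (group maps, COV/PV maps,
#' gradient magnitudes) as GIFTI metric files, the configuration as YAML
#' and a plain-text run manifest. Identical configurations produce
#' byte-identical CSV outputs.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$tables)) {
    utils::write.csv(bundle$tables[[nm]],
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  utils::write.csv(as.data.frame(bundle$jaccard),
                   file.path(dir, "jaccard.csv"))
  contour_rows <- do.call(rbind, lapply(names(bundle$contours), function(p) {
    do.call(rbind, lapply(bundle$contours[[p]], function(ct) {
      if (!nrow(ct$contour)) return(NULL)
      data.frame(parameter = p, pct = ct$pct, threshold = ct$threshold,
                 v1 = ct$contour[, 1], v2 = ct$contour[, 2])
    }))
  }))
  utils::write.csv(contour_rows, file.path(dir, "contours.csv"),
                   row.names = FALSE)
  write_gifti_surface(bundle$mesh, file.path(dir, "phantom.surf.gii"))
  safe_name <- function(p) gsub("/", "_over_", p, fixed = TRUE)
  for (p in names(bundle$group_maps)) {
    write_gifti_metric(
      cbind(bundle$group_maps[[p]], bundle$cov_maps[[p]]$inter,
            bundle$cov_maps[[p]]$intra, bundle$pv_maps[[p]],
            bundle$gradient_maps[[p]]$magnitude),
      file.path(dir, paste0(safe_name(p), ".func.gii"))
    )
  }
  write_config(bundle$config, file.path(dir, "config.yaml"))
  writeLines(bundle$manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
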
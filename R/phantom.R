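#' Population parameters for the synthetic cortical phantom
#'
#' Defaults describe a plausible 7T cortical cohort with a variance
#' decomposition that mirrors what drives the relative reliability of the
#' six parameters in vivo:
#'
#' * central depth-averaged R1 rises with myelination class while T2*
#'   falls (heavy areas carry more myelin and iron);
#' * the fine-grained myelin topography is a smooth multiplicative random
#'   field *shared by all subjects* (seeded by `population_seed`), on top
#'   of which each subject carries a smaller smooth deviation field and
#'   region-level log-normal factors;
#' * quantitative R1 is calibration-stable across subjects (small global
#'   factor), whereas T2* carries a sizeable subject-level global factor
#'   emulating its sensitivity to B0 shim and head orientation;
#' * the weighted T1w reconstruction carries a subject-level intensity
#'   gain (weighted images are in arbitrary units and are the least
#'   stable across subjects);
#' * depth profiles are linear in depth fraction, R1 falling and T2*
#'   rising toward the pial surface; the T2* field mixes a myelin-shared
#'   (anticorrelated) component dominating at deep fractions with an
#'   independent component growing toward the pial surface, so the
#'   R1--T2* anticorrelation weakens from the white-matter boundary to
#'   the pial surface;
#' * a small set of vertices at fixed (population-level) locations
#'   carries vein artifacts with T2* depressed below the 0.024 s
#'   exclusion threshold.
#'
#' The within-region field amplitude is calibrated so the
#' full-width-half-maximum of the depth-averaged cortical R1 distribution
#' is of the order of 0.05 s^-1.
#'
#' @param r1_central Named central R1 values (s^-1) per myelination class.
#' @param t2s_central Named central T2* values (s) per class.
#' @param inter_subject_sd SD of the per-region log-normal subject
#'   factors (both parameter families).
#' @param global_sd_r1,global_sd_t2s SD of the whole-map log-normal
#'   subject factors per family.
#' @param t1w_gain_sd SD of the subject-level multiplicative intensity
#'   gain applied to the weighted T1w reconstruction.
#' @param spatial_sd Amplitude of the shared (population) smooth
#'   log-scale field.
#' @param subject_spatial_sd Amplitude of the per-subject smooth
#'   deviation field.
#' @param spatial_fwhm_mm Smoothness scale (mm) of the random fields.
#' @param r1_depth_slope,t2s_depth_slope Fractional change of each
#'   parameter across the full cortical depth (signed; R1 negative).
#' @param shared_deep,shared_pial Weight of the myelin-shared T2*
#'   component at depth fractions 0 and 1.
#' @param indep_deep,indep_pial Weight of the independent T2* component
#'   at depth fractions 0 and 1.
#' @param vein_fraction Fraction of vertices flagged as vein artifacts
#'   (locations shared across subjects).
#' @param vein_t2s_range T2* range (s) assigned to vein vertices; below
#'   the exclusion threshold.
#' @param s0_mean,s0_sd Mean and SD of the proton-density-weighted echo
#'   amplitude S0 (a.u.).
#' @param curvature_coupling Multiplicative log-scale coefficient
#'   coupling R1 to standardized mesh curvature (injected so curvature
#'   residualization has a real effect to remove).
#' @param population_seed Seed of the shared anatomy (fields and vein
#'   locations).
#' @return A `population_params` list.
#' @export
population_params <- function(r1_central = c(heavy = 0.62, moderate = 0.57,
                                             light = 0.52),
                              t2s_central = c(heavy = 0.029,
                                              moderate = 0.032,
                                              light = 0.035),
                              inter_subject_sd = 0.025,
                              global_sd_r1 = 0.01,
                              global_sd_t2s = 0.09,
                              t1w_gain_sd = 0.07,
                              spatial_sd = 0.04,
                              subject_spatial_sd = 0.015,
                              spatial_fwhm_mm = 2.0,
                              r1_depth_slope = -0.15,
                              t2s_depth_slope = 0.12,
                              shared_deep = 1.0, shared_pial = 0.25,
                              indep_deep = 0.2, indep_pial = 1.2,
                              vein_fraction = 0.01,
                              vein_t2s_range = c(0.012, 0.022),
                              s0_mean = 100, s0_sd = 5,
                              curvature_coupling = 0.02,
                              population_seed = 20L) {
  if (any(r1_central <= 0) || any(t2s_central <= 0)) {
    stop("central R1/T2* values must be positive", call. = FALSE)
  }
  cls <- c("heavy", "moderate", "light")
  if (!all(cls %in% names(r1_central)) || !all(cls %in% names(t2s_central))) {
    stop("central values must be named heavy/moderate/light", call. = FALSE)
  }
  structure(
    list(r1_central = r1_central, t2s_central = t2s_central,
         inter_subject_sd = inter_subject_sd,
         global_sd_r1 = global_sd_r1, global_sd_t2s = global_sd_t2s,
         t1w_gain_sd = t1w_gain_sd,
         spatial_sd = spatial_sd, subject_spatial_sd = subject_spatial_sd,
         spatial_fwhm_mm = spatial_fwhm_mm,
         r1_depth_slope = r1_depth_slope, t2s_depth_slope = t2s_depth_slope,
         shared_deep = shared_deep, shared_pial = shared_pial,
         indep_deep = indep_deep, indep_pial = indep_pial,
         vein_fraction = vein_fraction, vein_t2s_range = vein_t2s_range,
         s0_mean = s0_mean, s0_sd = s0_sd,
         curvature_coupling = curvature_coupling,
         population_seed = population_seed),
    class = "population_params"
  )
}

# shared anatomy: population fields and vein locations (mesh + pop seed)
population_anatomy <- function(mesh, population) {
  n <- nrow(mesh$vertices)
  with_seed(population$population_seed, {
    list(
      g_mye = smooth_unit_field(mesh, stats::rnorm(n),
                                population$spatial_fwhm_mm),
      g_ind = smooth_unit_field(mesh, stats::rnorm(n),
                                population$spatial_fwhm_mm),
      vein_flag = stats::runif(n) < population$vein_fraction
    )
  })
}

#' Sample ground-truth relaxometry maps for one subject
#'
#' Deterministic in `(mesh, atlas, population, subject_seed)`. Produces
#' per-vertex R1 (s^-1) and T2* (s) at the 11 depth fractions, the echo
#' amplitude S0, vein flags (locations shared across subjects) and the
#' subject's weighted-intensity gain.
#'
#' @param mesh A `surface_mesh`.
#' @param atlas An `roi_atlas` on the same mesh.
#' @param population A [population_params()] list.
#' @param subject_seed Integer seed identifying the subject.
#' @return A `ground_truth_maps` object: `r1_true`, `t2s_true` (vertices x
#'   11 matrices), `s0_true`, `vein_flag`, `t1w_gain`.
#' @export
sample_ground_truth <- function(mesh, atlas, population = population_params(),
                                subject_seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(atlas, "roi_atlas"))
  pop <- population
  n <- nrow(mesh$vertices)
  fr <- depth_fractions()
  labels <- atlas$labels
  tab <- atlas$table
  cls <- tab$class[match(labels, tab$label)]
  anat <- population_anatomy(mesh, pop)

  with_seed(subject_seed, {
    # region-level multiplicative subject factors (log-normal)
    n_lab <- nrow(tab)
    fac_r1 <- exp(stats::rnorm(n_lab, 0, pop$inter_subject_sd))
    fac_t2s <- exp(stats::rnorm(n_lab, 0, pop$inter_subject_sd))
    v_fac_r1 <- fac_r1[match(labels, tab$label)]
    v_fac_t2s <- fac_t2s[match(labels, tab$label)]
    glob_r1 <- exp(stats::rnorm(1, 0, pop$global_sd_r1))
    glob_t2s <- exp(stats::rnorm(1, 0, pop$global_sd_t2s))
    t1w_gain <- exp(stats::rnorm(1, 0, pop$t1w_gain_sd))

    # subject deviation fields on top of the shared anatomy
    d_mye <- smooth_unit_field(mesh, stats::rnorm(n), pop$spatial_fwhm_mm)
    d_ind <- smooth_unit_field(mesh, stats::rnorm(n), pop$spatial_fwhm_mm)
    f_mye <- pop$spatial_sd * anat$g_mye + pop$subject_spatial_sd * d_mye
    f_ind <- pop$spatial_sd * anat$g_ind + pop$subject_spatial_sd * d_ind

    curv_z <- mesh$curvature
    if (stats::sd(curv_z) > 0) {
      curv_z <- (curv_z - mean(curv_z)) / stats::sd(curv_z)
    } else {
      curv_z <- rep(0, n)
    }

    r1_base <- pop$r1_central[cls] * v_fac_r1 * glob_r1 *
      exp(f_mye + pop$curvature_coupling * curv_z)
    t2s_base <- pop$t2s_central[cls] * v_fac_t2s * glob_t2s

    r1_true <- outer(r1_base, 1 + pop$r1_depth_slope * (fr - 0.5))
    w_sh <- pop$shared_deep + (pop$shared_pial - pop$shared_deep) * fr
    w_in <- pop$indep_deep + (pop$indep_pial - pop$indep_deep) * fr
    depth_field <- outer(-f_mye, w_sh) + outer(f_ind, w_in)
    t2s_true <- outer(t2s_base, 1 + pop$t2s_depth_slope * (fr - 0.5)) *
      exp(depth_field)

    vein_flag <- anat$vein_flag
    if (any(vein_flag)) {
      t2s_true[vein_flag, ] <- stats::runif(sum(vein_flag),
                                            pop$vein_t2s_range[1],
                                            pop$vein_t2s_range[2])
    }
    s0_true <- pmax(pop$s0_mean + stats::rnorm(n, 0, pop$s0_sd),
                    pop$s0_mean / 10)

    dimnames(r1_true) <- NULL
    dimnames(t2s_true) <- NULL
    structure(
      list(r1_true = r1_true, t2s_true = t2s_true,
           s0_true = unname(s0_true), vein_flag = vein_flag,
           t1w_gain = t1w_gain),
      class = "ground_truth_maps"
    )
  })
}

# iid field smoothed on the mesh, then re-standardized to zero mean / unit sd
smooth_unit_field <- function(mesh, z, fwhm_mm) {
  s <- geodesic_smooth(mesh, z, fwhm_mm)
  (s - mean(s)) / stats::sd(s)
}

#' Acquisition specification
#'
#' Echo times and scan durations default to a two-sequence 7T protocol:
#' four gradient-echo readouts at 2.53/7.03/12.55/20.35 ms (8:33 min) for
#' the transversal parameters and an MP2RAGE-like acquisition (8:02 min)
#' for the longitudinal ones; ratio parameters cost the sum of both.
#'
#' @param echo_times Echo times in seconds, strictly increasing.
#' @param scan_minutes Named vector with elements `t1` and `gre` (minutes).
#' @param noise_sd_gre SD of the additive Gaussian noise on echo
#'   magnitudes (a.u.).
#' @param noise_sd_t1 SD of the additive noise on the R1 measurement
#'   (s^-1).
#' @param transform Parameters of the [weighted_transform()].
#' @return An `acquisition_spec` object.
#' @export
acquisition_spec <- function(echo_times = c(2.53, 7.03, 12.55, 20.35) / 1000,
                             scan_minutes = c(t1 = 8 + 2 / 60,
                                              gre = 8 + 33 / 60),
                             noise_sd_gre = 2.5,
                             noise_sd_t1 = 0.008,
                             transform = weighted_transform_params()) {
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0)) {
    stop("echo times must be positive and strictly increasing",
         call. = FALSE)
  }
  if (!all(c("t1", "gre") %in% names(scan_minutes)) ||
      any(scan_minutes <= 0)) {
    stop("scan_minutes must be positive and named t1/gre", call. = FALSE)
  }
  structure(
    list(echo_times = echo_times, scan_minutes = scan_minutes,
         noise_sd_gre = noise_sd_gre, noise_sd_t1 = noise_sd_t1,
         transform = transform),
    class = "acquisition_spec"
  )
}

#' Scan minutes attributed to a parameter
#'
#' Longitudinal parameters (R1, T1w) cost the T1-source acquisition,
#' transversal ones (T2*, T2*w) the gradient-echo acquisition, and ratios
#' the sum of both, reflecting total scan cost.
#'
#' @param parameter One of `"R1"`, `"T1w"`, `"T2s"`, `"T2sw"`,
#'   `"T1w/T2sw"`, `"R1/T2s"`.
#' @param acq An [acquisition_spec()].
#' @return Minutes (numeric scalar).
#' @export
scan_minutes_for <- function(parameter, acq) {
  sm <- acq$scan_minutes
  switch(parameter,
         "R1" = , "T1w" = unname(sm["t1"]),
         "T2s" = , "T2sw" = unname(sm["gre"]),
         "T1w/T2sw" = , "R1/T2s" = unname(sm["t1"] + sm["gre"]),
         stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE))
}

#' Parameters of the weighted longitudinal transform
#'
#' @param center Sigmoid center on the R1 axis (s^-1).
#' @param width Sigmoid width (s^-1); smaller widths spread the central
#'   part of the R1 range over a broader relative T1w range.
#' @param scale,offset Output scale and offset (a.u.).
#' @param bias_field Optional multiplicative per-vertex bias field
#'   (default off).
#' @return A `weighted_transform_params` list.
#' @export
weighted_transform_params <- function(center = 0.54, width = 0.07,
                                      scale = 800, offset = 200,
                                      bias_field = NULL) {
  structure(list(center = center, width = width, scale = scale,
                 offset = offset, bias_field = bias_field),
            class = "weighted_transform_params")
}

#' Map quantitative R1 to a T1-weighted intensity
#'
#' Strictly monotone sigmoidal intensity transform emulating how a
#' weighted acquisition translates a given quantitative range into a
#' broader relative intensity range near the center of its dynamic range
#' while compressing the tails. Output is in arbitrary units; with the
#' default phantom the rescaled-distribution FWHM of T1w exceeds that of
#' R1.
#'
#' @param r1 Per-vertex R1 values (s^-1), strictly positive.
#' @param params A [weighted_transform_params()] list.
#' @return Per-vertex T1w intensities (a.u.).
#' @export
weighted_transform <- function(r1, params = weighted_transform_params()) {
  bad <- is.finite(r1) & r1 <= 0
  if (any(bad)) stop("R1 values must be strictly positive", call. = FALSE)
  out <- params$offset +
    params$scale * stats::plogis((r1 - params$center) / params$width)
  if (!is.null(params$bias_field)) {
    if (length(params$bias_field) != length(r1)) {
      stop("bias field length must match the map", call. = FALSE)
    }
    out <- out * params$bias_field
  }
  out
}

#' Simulate one acquisition session
#'
#' Generates 4-echo gradient-echo magnitudes S0 exp(-TE/T2*_true) plus
#' zero-mean Gaussian noise (Gaussian approximation of magnitude noise at
#' high SNR), an R1 measurement with additive Gaussian noise, the
#' T1-weighted transform of the measured R1 (scaled by the subject's
#' weighted-intensity gain), and fills all six derived parameter maps
#' (T2* mono-exponential fit, T2*w echo ratio, both ratio images) per
#' depth and depth-averaged over the default 20--80% window.
#' Deterministic in `session_seed`.
#'
#' @param gt A `ground_truth_maps` object.
#' @param acq An [acquisition_spec()].
#' @param session_seed Integer seed for this session's noise.
#' @param subject_id,session_id Identifiers carried through to outputs.
#' @return A `subject_session` object with `echoes` (vertices x echoes x
#'   depths array) and `maps`: per parameter a list with `depths`
#'   (vertices x 11) and `avg` (per-vertex depth average).
#' @export
simulate_session <- function(gt, acq, session_seed = 1L,
                             subject_id = "S01", session_id = 1L) {
  stopifnot(inherits(gt, "ground_truth_maps"),
            inherits(acq, "acquisition_spec"))
  te <- acq$echo_times
  n <- length(gt$s0_true)
  n_depth <- ncol(gt$t2s_true)
  n_echo <- length(te)
  gain <- if (is.null(gt$t1w_gain)) 1 else gt$t1w_gain

  with_seed(session_seed, {
    echoes <- array(NA_real_, dim = c(n, n_echo, n_depth))
    for (d in seq_len(n_depth)) {
      clean <- gt$s0_true * exp(outer(-1 / gt$t2s_true[, d], te))
      echoes[, , d] <- clean +
        matrix(stats::rnorm(n * n_echo, 0, acq$noise_sd_gre), n, n_echo)
    }
    r1_meas <- gt$r1_true +
      matrix(stats::rnorm(n * n_depth, 0, acq$noise_sd_t1), n, n_depth)

    t1w <- apply_cols(r1_meas, function(col) {
      # noise can push R1 non-positive in principle; mark unfittable
      out <- rep(NA_real_, length(col))
      ok <- is.finite(col) & col > 0
      out[ok] <- gain * weighted_transform(col[ok], acq$transform)
      out
    })

    t2s <- matrix(NA_real_, n, n_depth)
    t2sw <- matrix(NA_real_, n, n_depth)
    for (d in seq_len(n_depth)) {
      es <- echo_series(echoes[, , d], te)
      t2s[, d] <- fit_t2star(es)$t2s
      t2sw[, d] <- t2star_weighted(es)
    }
    rat <- ratio_maps(t1w, t2sw, r1_meas, t2s)

    maps <- list(
      "R1" = r1_meas, "T1w" = t1w, "T2s" = t2s, "T2sw" = t2sw,
      "T1w/T2sw" = rat$t1w_t2sw, "R1/T2s" = rat$r1_t2s
    )
    maps <- lapply(maps, function(m) {
      m[!is.finite(m)] <- NA_real_
      list(depths = m, avg = depth_average(m))
    })
    structure(
      list(subject_id = subject_id, session_id = session_id,
           echoes = echoes, maps = maps),
      class = "subject_session"
    )
  })
}

apply_cols <- function(m, f) {
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- f(m[, j])
  out
}

#' Names of the six analysed parameters
#'
#' @return Character vector in canonical order.
#' @export
parameter_names <- function() {
  c("R1", "T1w", "T2s", "T2sw", "T1w/T2sw", "R1/T2s")
}
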
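#' Capture conditions for the angle-validity experiment
#'
#' The four capture geometries of the validity design: directly above the
#' sample at 0, 10 and 20 degrees of pitch, and a 33-degree pitch with a
#' 10 cm setback (standing back from the bench). A pitched camera at fixed
#' height swings its view away from the sample, so to keep the tube centred
#' in the frame the pitched "directly above" conditions offset the camera
#' by `height * tan(pitch)` along the tube axis -- the same recentring the
#' setback condition makes explicit. Set `recenter = FALSE` to keep setback
#' 0 for the pitched conditions (with the default optics the tube then
#' leaves the field of view, so this is only useful with a wide-angle
#' [camera_intrinsics()]).
#'
#' @param height_cm Camera height (cm).
#' @param recenter Recentre pitched conditions (default `TRUE`).
#' @return Named list of [camera_pose()] objects
#'   (`nadir`, `pitch10`, `pitch20`, `pitch33_setback10`).
#' @export
validity_conditions <- function(height_cm = 19.5, recenter = TRUE) {
  sb <- function(deg) if (recenter) height_cm * tan(deg * pi / 180) else 0
  list(
    nadir = camera_pose(height_cm = height_cm),
    pitch10 = camera_pose(pitch_deg = 10, height_cm = height_cm,
                          setback_cm = sb(10)),
    pitch20 = camera_pose(pitch_deg = 20, height_cm = height_cm,
                          setback_cm = sb(20)),
    pitch33_setback10 = camera_pose(pitch_deg = 33, height_cm = height_cm,
                                    setback_cm = 10)
  )
}

#' In-silico replication of the capture-angle validity experiment
#'
#' Renders every sample under every capture condition, measures each image
#' with the automatic marker detection (falling back to the rendered ground
#' truth markers if detection fails), and runs the full validity analysis:
#' repeated-measures ANOVA over the app conditions, Bonferroni paired t
#' tests of each condition against the nadir reference, and Bland-Altman
#' agreement of every condition (and the simulated mechanical reader)
#' against nadir. The mechanical-reader reference is the true hematocrit
#' read to the nearest 0.5 division after optional zero-mean reader noise.
#'
#' @param n_samples Number of simulated blood samples (>= 2).
#' @param conditions Named list of [camera_pose()]s including a nadir
#'   reference (pitch and setback ~0); see [validity_conditions()].
#' @param hct_range True hematocrit interval sampled uniformly.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param cfg A [render_config()].
#' @param tube Template [tube_spec()].
#' @param measure `"detect"` (render then detect markers) or `"truth"`
#'   (skip detection and read the ground-truth markers; faster).
#' @param mhr_noise_sd SD of the simulated reader's zero-mean reading noise
#'   before quantisation to 0.5 (default 0.25, half a credible division).
#' @param fill_sd_mm SD of per-sample variation in the tube fill length
#'   (mm, default 1.5): finger-prick columns differ from draw to draw, and
#'   this variation also keeps the pixel quantisation of the marker rows
#'   from repeating identically across samples, as it never would across
#'   real tubes.
#' @return A `validity_simulation` object: list with `measurements` (long
#'   tibble: sample_id, method, hct_pct, true_hct_pct), `anova`,
#'   `pairwise`, `bland_altman` (named list vs nadir), `conditions`,
#'   `seed`.
#' @export
run_validity_simulation <- function(n_samples = 20,
                                    conditions = validity_conditions(),
                                    hct_range = c(38, 48), seed = 1L,
                                    cfg = render_config(),
                                    tube = tube_spec(),
                                    measure = c("detect", "truth"),
                                    mhr_noise_sd = 0.25, fill_sd_mm = 1.5) {
  measure <- match.arg(measure)
  n_samples <- as.integer(check_number(n_samples, "n_samples"))
  if (n_samples < 2) {
    stop_microhct("`n_samples` must be >= 2.", "microhct_invalid_config")
  }
  if (length(conditions) < 2 || is.null(names(conditions)) ||
      any(!nzchar(names(conditions)))) {
    stop_microhct("`conditions` must be a named list of >= 2 camera poses.",
                  "microhct_invalid_config")
  }
  is_nadir <- vapply(conditions, function(p) {
    abs(p$pitch_deg) < 1e-6 && abs(p$yaw_deg) < 1e-6 && p$setback_cm < 1e-6
  }, logical(1))
  if (!any(is_nadir)) {
    stop_microhct("`conditions` must include a nadir reference (pitch, yaw, setback all 0).",
                  "microhct_invalid_config")
  }
  reference <- names(conditions)[which(is_nadir)[1]]

  withr::local_seed(as.integer(seed))
  true_hct <- runif(n_samples, hct_range[1], hct_range[2])
  fills <- pmax(tube$fill_length_mm / 2,
                rnorm(n_samples, tube$fill_length_mm, fill_sd_mm))
  sample_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, n_samples * length(conditions)),
    nrow = n_samples)
  mhr <- round((true_hct + rnorm(n_samples, 0, mhr_noise_sd)) / 0.5) * 0.5
  mhr <- pmin(pmax(mhr, 0), 100)

  ids <- sprintf("S%02d", seq_len(n_samples))
  rows <- list()
  for (i in seq_len(n_samples)) {
    tb <- tube
    tb$true_hct_pct <- true_hct[i]
    tb$fill_length_mm <- fills[i]
    for (j in seq_along(conditions)) {
      cf <- cfg
      cf$seed <- sample_seeds[i, j]
      rs <- render_tube(tb, conditions[[j]], cf)
      hct <- if (measure == "truth") {
        compute_hct(rs$truth_markers)$hct_pct
      } else {
        tryCatch(
          compute_hct(detect_markers(rs$image, cf)$markers)$hct_pct,
          microhct_error = function(e) compute_hct(rs$truth_markers)$hct_pct
        )
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = ids[i], method = names(conditions)[j],
        hct_pct = hct, true_hct_pct = true_hct[i])
    }
  }
  meas <- dplyr::bind_rows(rows)
  meas <- dplyr::bind_rows(
    meas,
    tibble::tibble(sample_id = ids, method = "MHR", hct_pct = mhr,
                   true_hct_pct = true_hct)
  )

  app <- meas[meas$method != "MHR", ]
  anova_res <- rm_anova(app, within = "method")
  others <- setdiff(names(conditions), reference)
  pairwise <- paired_t_bonferroni(
    app, comparisons = purrr::map(others, ~ c(.x, reference)),
    within = "method")
  ref_vals <- app$hct_pct[app$method == reference][
    match(ids, app$sample_id[app$method == reference])]
  ba <- purrr::map(c(others, "MHR"), function(m) {
    v <- meas$hct_pct[meas$method == m][match(ids, meas$sample_id[meas$method == m])]
    bland_altman(v, ref_vals)
  })
  names(ba) <- c(others, "MHR")

  structure(
    list(measurements = meas, anova = anova_res, pairwise = pairwise,
         bland_altman = ba, conditions = conditions, reference = reference,
         seed = as.integer(seed), measure = measure),
    class = "validity_simulation"
  )
}

#' @export
print.validity_simulation <- function(x, ...) {
  n <- length(unique(x$measurements$sample_id))
  cat(sprintf("<validity_simulation> %d samples x %d conditions (+MHR), seed %d\n",
              n, length(x$conditions), x$seed))
  cat(sprintf("  ANOVA: F(%g, %g) = %.2f, p = %.3g, partial eta^2 = %.3f (%s)\n",
              x$anova$df1, x$anova$df2, x$anova$statistic, x$anova$p_value,
              x$anova$partial_eta_sq, x$anova$band))
  for (m in names(x$bland_altman)) {
    b <- x$bland_altman[[m]]
    cat(sprintf("  %s vs %s: mean diff %+.2f [LOA %+.2f, %+.2f] -> %s agreement\n",
                m, x$reference, b$mean_diff, b$loa_low, b$loa_high,
                if (b$good_agreement) "good" else "poor"))
  }
  invisible(x)
}
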
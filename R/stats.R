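#' Bland-Altman agreement analysis
#'
#' Computes the mean difference between two paired measurement series and
#' the 95% limits of agreement, `mean(d) +/- 1.96 * sd(d)` with the sample
#' (n-1) standard deviation of the differences `d = x - y`. Agreement is
#' flagged good when the absolute mean difference is below `threshold`
#' percentage points; the default 1.2 comes from the equivalence argument
#' that 1.2% of a typical hematocrit of 45 is 0.5 points -- the smallest
#' difference a mechanical reader can credibly resolve.
#'
#' @param x,y Paired numeric vectors (equal length, n >= 2).
#' @param threshold Good-agreement bound on `|mean difference|` (percentage
#'   points).
#' @return A `bland_altman` object: list with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `good_agreement`, `threshold`, `n`, and a
#'   `pairs` tibble (`mean`, `diff`) for plotting.
#' @examples
#' ba <- bland_altman(c(42, 44, 46), c(41, 42, 43))
#' ba$mean_diff   # 2
#' @export
bland_altman <- function(x, y, threshold = 1.2) {
  if (length(x) != length(y)) {
    stop_microhct("`x` and `y` must be paired (equal length).",
                  "microhct_insufficient_data")
  }
  if (length(x) < 2) {
    stop_microhct("Bland-Altman needs at least 2 pairs.",
                  "microhct_insufficient_data")
  }
  d <- x - y
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  structure(
    list(mean_diff = mean_diff, sd_diff = sd_diff,
         loa_low = mean_diff - 1.96 * sd_diff,
         loa_high = mean_diff + 1.96 * sd_diff,
         good_agreement = abs(mean_diff) < threshold,
         threshold = threshold, n = length(x),
         pairs = tibble::tibble(mean = (x + y) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> mean diff %.3f, LOA [%.3f, %.3f], %s agreement (n = %d)\n",
    x$mean_diff, x$loa_low, x$loa_high,
    if (x$good_agreement) "good" else "poor", x$n))
  invisible(x)
}

#' Intraclass correlation and typical error
#'
#' Reliability of repeated hematocrit measurements from a balanced subjects
#' x measurements grid. The default form is the two-way absolute-agreement
#' single-measure ICC (ICC(A,1)), computed from the two-way mean squares;
#' absolute agreement matches the use of ICC alongside Bland-Altman, where
#' a systematic shift between raters should count against reliability.
#' Consistency (ICC(C,1)) and one-way (ICC(1,1)) forms are available. The
#' 95% confidence interval uses the standard F-based constructions
#' (McGraw-Wong). Typical error is the sports-science convention: the SD of
#' between-measurement difference scores divided by sqrt(2), averaged over
#' measurement pairs when there are more than two.
#'
#' @param data A [trial_table()] (or any long data frame with `sample_id`
#'   and the measurement/value columns).
#' @param design `"intra"`: measurements are the repeated trials of one
#'   rater+method (the table must contain exactly one rater and method, or
#'   be filtered with `rater=`/`method=`); `"inter"`: measurements are the
#'   raters' definitive values (trial means) for each sample.
#' @param type ICC form: `"agreement"` (default), `"consistency"`, `"oneway"`.
#' @param rater,method Optional filters applied before analysis.
#' @param conf_level Confidence level for the interval.
#' @return An `icc_reliability` object: list with `icc`, `conf_low`,
#'   `conf_high`, `typical_error`, `design`, `type`, `n`, `k`, `degenerate`
#'   and the mean squares.
#' @export
icc <- function(data, design = c("intra", "inter"),
                type = c("agreement", "consistency", "oneway"),
                rater = NULL, method = NULL, conf_level = 0.95) {
  design <- match.arg(design)
  type <- match.arg(type)
  if (!is.null(rater)) data <- data[data$rater %in% rater, ]
  if (!is.null(method)) data <- data[data$method %in% method, ]
  if (design == "intra") {
    if (length(unique(data$rater)) != 1 || length(unique(data$method)) != 1) {
      stop_microhct("Intra-rater design needs a single rater and method (use `rater=`/`method=`).",
                    "microhct_design_error")
    }
    m <- trial_matrix(data, "trial")
  } else {
    if (length(unique(data$rater)) < 2) {
      stop_microhct("Inter-rater design needs at least two raters.",
                    "microhct_design_error")
    }
    agg <- dplyr::summarise(dplyr::group_by(data, .data$sample_id, .data$rater),
                            hct_pct = mean(.data$hct_pct), .groups = "drop")
    m <- trial_matrix(agg, "rater")
  }
  icc_matrix(m, type = type, conf_level = conf_level, design = design)
}

# Core computation on an n x k matrix (subjects x measurements).
icc_matrix <- function(m, type = "agreement", conf_level = 0.95,
                       design = "intra") {
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) {
    stop_microhct("ICC needs at least 2 subjects and 2 measurements.",
                  "microhct_design_error")
  }
  g <- mean(m)
  ssr <- k * sum((rowMeans(m) - g)^2)
  ssc <- n * sum((colMeans(m) - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level

  degenerate <- sst < 1e-12
  if (degenerate) {
    est <- NA_real_; lo <- NA_real_; hi <- NA_real_
  } else if (type == "agreement") {
    est <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    vnum <- (a * msc + b * mse)^2
    vden <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
    if (is.finite(vnum) && vden > 0) {
      v <- vnum / vden
      fl <- qf(1 - alpha / 2, n - 1, v)
      fu <- qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
    } else {
      lo <- NA_real_; hi <- NA_real_
    }
  } else if (type == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse > 0) {
      fobs <- msr / mse
      fl <- fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    } else {
      lo <- NA_real_; hi <- NA_real_
    }
  } else { # oneway
    msw <- (ssc + sse) / (n * (k - 1))
    est <- (msr - msw) / (msr + (k - 1) * msw)
    if (msw > 0) {
      fobs <- msr / msw
      fl <- fobs / qf(1 - alpha / 2, n - 1, n * (k - 1))
      fu <- fobs * qf(1 - alpha / 2, n * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    } else {
      lo <- NA_real_; hi <- NA_real_
    }
  }
  if (!degenerate) {
    lo <- min(max(lo, -1), est, na.rm = FALSE)
    hi <- max(min(hi, 1), est, na.rm = FALSE)
  }

  pairs <- utils::combn(k, 2)
  te <- mean(apply(pairs, 2, function(j) sd(m[, j[1]] - m[, j[2]]) / sqrt(2)))

  structure(
    list(icc = est, conf_low = lo, conf_high = hi, typical_error = te,
         design = design, type = type, n = n, k = k,
         degenerate = degenerate,
         ms = list(msr = msr, msc = msc, mse = mse),
         conf_level = conf_level),
    class = "icc_reliability"
  )
}

#' @export
print.icc_reliability <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<icc_reliability> undefined (zero total variance); typical error %.3f\n",
                x$typical_error))
  } else {
    cat(sprintf(
      "<icc_reliability> ICC(%s, single) = %.3f [%.0f%% CI %.3f-%.3f], typical error %.3f (%s, n = %d, k = %d)\n",
      x$type, x$icc, 100 * x$conf_level, x$conf_low, x$conf_high,
      x$typical_error, x$design, x$n, x$k))
  }
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor.test()] returning a tidy one-row result;
#' errors (rather than returning `NA`) when either vector has zero variance.
#'
#' @param x,y Numeric vectors, `n >= 3`, finite.
#' @return One-row tibble with `r`, `p_value`, `n`, `conf_low`, `conf_high`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3 ||
      any(!is.finite(x)) || any(!is.finite(y))) {
    stop_microhct("`x` and `y` must be finite, paired, with n >= 3.",
                  "microhct_insufficient_data")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_microhct("Correlation is undefined for a zero-variance vector.",
                  "microhct_undefined_correlation")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
                 conf_low = ct$conf.int[1], conf_high = ct$conf.int[2])
}

band_eta <- function(e) {
  if (e >= 0.26) "large" else if (e >= 0.13) "medium"
  else if (e >= 0.02) "small" else "negligible"
}

band_d <- function(d) {
  a <- abs(d)
  if (a >= 0.8) "large" else if (a >= 0.5) "medium"
  else if (a >= 0.2) "small" else "negligible"
}

#' One-way repeated-measures ANOVA with partial eta squared
#'
#' Subject-blocked one-way ANOVA on a complete subjects x conditions grid,
#' as used to test an effect of capture condition on measured hematocrit.
#' The effect size is partial eta squared, `SS_effect / (SS_effect +
#' SS_error)`, interpreted on the 0.02 / 0.13 / 0.26 small-medium-large
#' bands. Sphericity is not corrected by default; set
#' `greenhouse_geisser = TRUE` to adjust the degrees of freedom by the
#' Greenhouse-Geisser epsilon.
#'
#' @param data Long data frame with subject, condition and value columns.
#' @param within Name of the condition (within-subject) column.
#' @param subject,value Column names (defaults `sample_id`, `hct_pct`).
#' @param greenhouse_geisser Apply the Greenhouse-Geisser correction.
#' @return An `rm_anova` object: one-row tibble with `statistic` (F),
#'   `df1`, `df2`, `p_value`, `partial_eta_sq`, `band`, plus attributes
#'   carrying the sums of squares.
#' @export
rm_anova <- function(data, within = "condition", subject = "sample_id",
                     value = "hct_pct", greenhouse_geisser = FALSE) {
  df <- data.frame(
    subject = factor(data[[subject]]),
    condition = factor(data[[within]]),
    y = as.numeric(data[[value]])
  )
  tab <- table(df$subject, df$condition)
  if (any(tab != 1)) {
    stop_microhct("Design must be complete: one value per subject x condition.",
                  "microhct_design_error")
  }
  fit <- aov(y ~ condition + Error(subject), data = df)
  sm <- summary(fit)
  st <- sm[["Error: Within"]][[1]]
  ss_sub <- sm[["Error: subject"]][[1]]["Residuals", "Sum Sq"]
  ss_eff <- st["condition", "Sum Sq"]
  ss_err <- st["Residuals", "Sum Sq"]
  df1 <- st["condition", "Df"]
  df2 <- st["Residuals", "Df"]
  # snap floating-point dust to zero (aov leaves ~1e-28 sums of squares on
  # exactly constant contrasts, which would otherwise produce a spurious
  # effect-size ratio)
  tol <- 1e-10 * max(1, ss_sub + ss_eff + ss_err)
  if (ss_eff < tol) ss_eff <- 0
  if (ss_err < tol) ss_err <- 0
  ms_eff <- ss_eff / df1
  ms_err <- ss_err / df2
  f <- if (ms_err > 0) ms_eff / ms_err else if (ms_eff > 0) Inf else 0
  eps <- 1
  if (greenhouse_geisser) {
    eps <- gg_epsilon(df)
  }
  p <- pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  eta <- if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0
  out <- tibble::tibble(
    statistic = f, df1 = df1 * eps, df2 = df2 * eps, p_value = p,
    partial_eta_sq = eta, band = band_eta(eta)
  )
  attr(out, "ss") <- list(effect = ss_eff, error = ss_err, epsilon = eps)
  class(out) <- c("rm_anova", class(out))
  out
}

# Greenhouse-Geisser epsilon from the subjects x conditions covariance.
gg_epsilon <- function(df) {
  m <- trial_matrix(
    tibble::tibble(sample_id = df$subject, cond = df$condition,
                   hct_pct = df$y),
    "cond")
  s <- stats::cov(m)
  k <- ncol(s)
  dbar <- mean(diag(s))
  sbar <- mean(s)
  srow <- rowMeans(s)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(s^2) - 2 * k * sum(srow^2) + k^2 * sbar^2)
  if (den <= 0) return(1)
  min(1, num / den)
}

#' Bonferroni-corrected paired t tests
#'
#' Post-hoc pairwise comparisons after [rm_anova()]: a two-sided paired t
#' test per requested condition pair, with Bonferroni adjustment
#' (`p_adj = min(1, p * m)` for `m` comparisons) and Cohen's d (pooled-SD
#' form) attached to each pair.
#'
#' @param data Long data frame as for [rm_anova()].
#' @param comparisons List of length-2 character vectors naming condition
#'   pairs; `NULL` compares every pair.
#' @param within,subject,value Column names.
#' @return Tibble with one row per comparison: `a`, `b`, `statistic`, `df`,
#'   `p_value`, `p_adjusted`, `cohens_d`, `band`.
#' @export
paired_t_bonferroni <- function(data, comparisons = NULL,
                                within = "condition", subject = "sample_id",
                                value = "hct_pct") {
  conds <- unique(as.character(data[[within]]))
  if (is.null(comparisons)) {
    comparisons <- utils::combn(conds, 2, simplify = FALSE)
  }
  if (length(comparisons) == 0) {
    stop_microhct("`comparisons` must name at least one condition pair.",
                  "microhct_invalid_argument")
  }
  m <- length(comparisons)
  rows <- purrr::map_dfr(comparisons, function(pr) {
    da <- data[data[[within]] == pr[1], c(subject, value)]
    db <- data[data[[within]] == pr[2], c(subject, value)]
    j <- match(da[[subject]], db[[subject]])
    if (anyNA(j) || nrow(da) != nrow(db) || nrow(da) < 2) {
      stop_microhct(sprintf("Comparison %s vs %s is not completely paired.",
                            pr[1], pr[2]),
                    "microhct_design_error")
    }
    a <- da[[value]]
    b <- db[[value]][j]
    dvec <- a - b
    if (sd(dvec) == 0) {
      tstat <- 0; p <- 1; dfree <- length(a) - 1
    } else {
      tt <- t.test(a, b, paired = TRUE)
      tstat <- unname(tt$statistic); p <- tt$p.value; dfree <- unname(tt$parameter)
    }
    d <- tryCatch(cohens_d(a, b)$cohens_d,
                  microhct_undefined_effect = function(e) 0)
    tibble::tibble(a = pr[1], b = pr[2], statistic = tstat, df = dfree,
                   p_value = p, p_adjusted = min(1, p * m),
                   cohens_d = d, band = band_d(d))
  })
  rows
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(a) - mean(b)) / s_p` with
#' `s_p = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`,
#' banded on `|d|` at 0.2 / 0.5 / 0.8 (small / medium / large).
#'
#' @param a,b Numeric vectors, each `n >= 2`.
#' @return One-row tibble with `cohens_d`, `band`, `pooled_sd`, `n_a`, `n_b`.
#' @examples
#' cohens_d(c(0, 2), c(2, 4))  # -sqrt(2), large
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2 || any(!is.finite(c(a, b)))) {
    stop_microhct("Both groups need n >= 2 finite values.",
                  "microhct_insufficient_data")
  }
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (sp == 0) {
    stop_microhct("Effect size is undefined when the pooled SD is zero.",
                  "microhct_undefined_effect")
  }
  d <- (mean(a) - mean(b)) / sp
  tibble::tibble(cohens_d = d, band = band_d(d), pooled_sd = sp,
                 n_a = na, n_b = nb)
}
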
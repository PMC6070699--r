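#' Parameters of cut-point computation
#'
#' @param alpha Target false-positive rate of the screening tier
#'   (default 0.05).
#' @param z_multiplier Normal quantile multiplier applied to the SD in
#'   parametric cut points (default 1.645, the upper 5\% point).
#' @param normality_alpha Shapiro-Wilk p-value below which the
#'   log-transformed data are declared non-normal and the parametric
#'   method falls back to the nonparametric 95th percentile (default
#'   0.10).
#' @param outlier_fence Multiple of the interquartile range beyond the
#'   quartiles at which values are removed as outliers (default 1.5).
#' @return A list of class `"cutpoint_params"`.
#' @export
cutpoint_params <- function(alpha = 0.05, z_multiplier = 1.645,
                            normality_alpha = 0.10, outlier_fence = 1.5) {
  check_fraction(alpha, "alpha", allow_zero = FALSE, allow_one = FALSE)
  if (outlier_fence <= 0) stop("outlier_fence must be > 0", call. = FALSE)
  structure(list(alpha = alpha, z_multiplier = z_multiplier,
                 normality_alpha = normality_alpha,
                 outlier_fence = outlier_fence),
            class = "cutpoint_params")
}

#' Remove interquartile-range outliers
#'
#' Single-pass Tukey fence: values outside
#' `[Q1 - fence * IQR, Q3 + fence * IQR]` are removed, with quartiles by
#' linear interpolation of order statistics (position `1 + p * (n - 1)`).
#' The fence is closed, so when the IQR is zero only values different
#' from the common quartile value are removed.
#'
#' @param values Numeric vector, length >= 4.
#' @param fence Fence multiplier (default 1.5).
#' @return List with `retained` and `removed` numeric vectors.
#' @export
remove_iqr_outliers <- function(values, fence = 1.5) {
  if (length(values) < 4) {
    stop("at least 4 values are required for outlier removal",
         call. = FALSE)
  }
  q1 <- interp_percentile(values, 0.25)
  q3 <- interp_percentile(values, 0.75)
  iqr <- q3 - q1
  keep <- values >= q1 - fence * iqr & values <= q3 + fence * iqr
  list(retained = values[keep], removed = values[!keep])
}

#' Shapiro-Wilk normality assessment
#'
#' @param values Numeric vector (3 to 5000 values; constant input is an
#'   error because the statistic is undefined).
#' @return The Shapiro-Wilk p-value.
#' @export
assess_normality <- function(values) {
  if (length(values) < 3 || length(values) > 5000) {
    stop("normality assessment requires 3 to 5000 values", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("normality is undefined for constant input", call. = FALSE)
  }
  stats::shapiro.test(values)$p.value
}

new_cutpoint_result <- function(cut_point, method, n_input,
                                n_outliers_removed, shapiro_p_raw = NA_real_,
                                shapiro_p_transformed = NA_real_,
                                notes = "") {
  structure(list(cut_point = cut_point, method = method,
                 n_input = n_input,
                 n_outliers_removed = n_outliers_removed,
                 shapiro_p_raw = shapiro_p_raw,
                 shapiro_p_transformed = shapiro_p_transformed,
                 notes = notes),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Cut point: %.4f (%s)\n", x$cut_point, x$method))
  cat(sprintf("  n = %d, outliers removed = %d\n", x$n_input,
              x$n_outliers_removed))
  if (!is.na(x$shapiro_p_raw)) {
    cat(sprintf("  Shapiro-Wilk p (raw) = %.4f\n", x$shapiro_p_raw))
  }
  if (!is.na(x$shapiro_p_transformed)) {
    cat(sprintf("  Shapiro-Wilk p (log) = %.4f\n", x$shapiro_p_transformed))
  }
  if (nzchar(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

# Shared validation of cut-point training sets.
check_training_values <- function(values, require_positive = FALSE) {
  if (length(values) < 10) {
    stop("at least 10 training samples are required", call. = FALSE)
  }
  if (length(values) < 48) {
    warning("fewer than 48 training samples; cut point may be unstable")
  }
  if (require_positive && any(values <= 0)) {
    stop("all OD values must be positive (blank-corrected and floored) ",
         "before cut-point computation", call. = FALSE)
  }
  invisible(values)
}

#' Screening cut point from untreated drug-naive sera (parametric)
#'
#' The classical parametric screening cut point: blank-corrected mean
#' ODs are log-transformed, normality of the transformed data is
#' assessed (Shapiro-Wilk), IQR outliers are removed on the log scale,
#' and the cut point is `exp(mean + z * SD)` of the retained logs, which
#' targets a false-positive rate of `alpha` (5\% for z = 1.645).  When
#' the log-transformed data still fail normality
#' (p <= `normality_alpha`) the method falls back to the nonparametric
#' 95th percentile of the raw values and records this in `notes`.
#'
#' @param values Blank-corrected mean ODs of the training sera (all
#'   positive; at least 10, conventionally 48).
#' @param params A [cutpoint_params()].
#' @return A `"cutpoint_result"` (see [new_cutpoint_result()] fields).
#' @seealso [screening_cutpoint_inhibited()] for the immune-inhibition
#'   variant, [confirmatory_cutpoint()] for the specificity tier.
#' @export
screening_cutpoint_untreated <- function(values,
                                         params = cutpoint_params()) {
  check_training_values(values, require_positive = TRUE)
  n <- length(values)
  if (stats::sd(values) == 0) {
    return(new_cutpoint_result(values[1], "parametric_log", n, 0L,
                               notes = "constant input; SD is 0"))
  }
  logs <- log(values)
  p_raw <- assess_normality(values)
  p_log <- assess_normality(logs)
  if (p_log <= params$normality_alpha) {
    out <- remove_iqr_outliers(values, params$outlier_fence)
    cut <- tail_percentile(out$retained, 1 - params$alpha)
    return(new_cutpoint_result(
      cut, "nonparametric_p95", n, length(out$removed),
      shapiro_p_raw = p_raw, shapiro_p_transformed = p_log,
      notes = paste0("log-transformed data failed normality (p = ",
                     signif(p_log, 4),
                     "); fell back to the 95th percentile")))
  }
  out <- remove_iqr_outliers(logs, params$outlier_fence)
  cut <- exp(mean(out$retained) +
               params$z_multiplier * stats::sd(out$retained))
  new_cutpoint_result(cut, "parametric_log", n, length(out$removed),
                      shapiro_p_raw = p_raw, shapiro_p_transformed = p_log)
}

#' Screening cut point from immune-inhibited sera (nonparametric)
#'
#' For populations with likely prior antigen exposure, the cut point is
#' computed from training sera pre-incubated with excess free antigen,
#' so that pre-existing specific antibodies do not inflate the
#' threshold.  Inhibited OD distributions are typically not
#' normalizable, so the method is nonparametric: IQR outliers are
#' removed on the raw scale and the cut point is the 95th percentile
#' (generally the `1 - alpha` quantile) of the retained values, by
#' linear interpolation of order statistics at the Weibull plotting
#' position `p * (n + 1)`.  That position makes the expected fraction of
#' fresh negative samples above the cut point equal to `alpha`, which is
#' the design goal of the screening tier.
#'
#' @inheritParams screening_cutpoint_untreated
#' @return A `"cutpoint_result"`.
#' @export
screening_cutpoint_inhibited <- function(values,
                                         params = cutpoint_params()) {
  check_training_values(values)
  n <- length(values)
  p_raw <- if (stats::sd(values) > 0) assess_normality(values) else NA_real_
  out <- remove_iqr_outliers(values, params$outlier_fence)
  cut <- tail_percentile(out$retained, 1 - params$alpha)
  new_cutpoint_result(cut, "nonparametric_p95", n, length(out$removed),
                      shapiro_p_raw = p_raw)
}

#' Percent inhibition by excess free antigen
#'
#' Percentage decrease of the blank-corrected OD caused by
#' pre-incubation with excess antigen:
#' `100 * (od_untreated - od_inhibited) / od_untreated`.  Values may be
#' negative (signal enhancement) and cannot exceed 100 for non-negative
#' inhibited ODs.
#'
#' @param od_untreated Blank-corrected OD without antigen competition
#'   (> 0).
#' @param od_inhibited Blank-corrected OD after competition.
#' @return Percent inhibition (vectorized).
#' @export
percent_inhibition <- function(od_untreated, od_inhibited) {
  if (any(od_untreated <= 0)) {
    stop("od_untreated must be > 0 (blank-corrected and floored)",
         call. = FALSE)
  }
  100 * (od_untreated - od_inhibited) / od_untreated
}

#' Confirmatory cut point on the percent-inhibition scale
#'
#' Minimum percent inhibition establishing antigen specificity: IQR
#' outliers are removed from the training inhibitions and the cut point
#' is `mean + z * SD` of the retained values (no log transform),
#' maintaining a nominal `alpha` false-positive rate in the confirmatory
#' tier.
#'
#' @param inhibitions Percent inhibitions of the training sera (at
#'   least 10).
#' @param params A [cutpoint_params()].
#' @return A `"cutpoint_result"` with method `"confirmatory_linear"`.
#' @export
confirmatory_cutpoint <- function(inhibitions,
                                  params = cutpoint_params()) {
  check_training_values(inhibitions)
  n <- length(inhibitions)
  p_raw <- if (stats::sd(inhibitions) > 0) assess_normality(inhibitions)
           else NA_real_
  out <- remove_iqr_outliers(inhibitions, params$outlier_fence)
  cut <- mean(out$retained) + params$z_multiplier * stats::sd(out$retained)
  if (length(out$retained) == 1 || stats::sd(out$retained) == 0) {
    cut <- mean(out$retained)
  }
  new_cutpoint_result(cut, "confirmatory_linear", n, length(out$removed),
                      shapiro_p_raw = p_raw)
}

#' Derive all three cut points from a training panel
#'
#' Convenience wrapper for one antigen's drug-naive training set:
#' computes the untreated parametric screening cut point from the
#' untreated mean ODs, the immune-inhibition nonparametric screening cut
#' point from the inhibited mean ODs, and the confirmatory cut point
#' from the paired percent inhibitions.
#'
#' @param samples Aggregated sample results ([aggregate_replicates()])
#'   for one antigen, containing conditions `"untreated"` and
#'   `"inhibited"` for every training donor.
#' @param params A [cutpoint_params()].
#' @return List with elements `untreated`, `inhibited`, `confirmatory`
#'   (each a `"cutpoint_result"`).
#' @export
train_cutpoints <- function(samples, params = cutpoint_params()) {
  if (length(unique(samples$antigen)) != 1) {
    stop("train_cutpoints expects samples for a single antigen",
         call. = FALSE)
  }
  unt <- samples[samples$condition == "untreated", ]
  inh <- samples[samples$condition == "inhibited", ]
  i <- match(unt$donor_id, inh$donor_id)
  if (anyNA(i)) {
    stop("missing inhibited condition for donor(s): ",
         paste(unt$donor_id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  list(untreated = screening_cutpoint_untreated(unt$mean_od, params),
       inhibited = screening_cutpoint_inhibited(inh$mean_od, params),
       confirmatory = confirmatory_cutpoint(
         percent_inhibition(unt$mean_od, inh$mean_od[i]), params))
}
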
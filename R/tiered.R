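.screening_methods <- c("parametric_log", "nonparametric_p95")

#' Screening-tier call for a sample
#'
#' A sample screens positive when its blank-corrected mean OD is
#' strictly above the screening cut point; a value exactly at the cut
#' point is negative.
#'
#' @param mean_od Blank-corrected mean OD(s).
#' @param cut_point A `"cutpoint_result"` from a screening method.
#' @return Logical vector of screening calls.
#' @export
screen_sample <- function(mean_od, cut_point) {
  stopifnot(inherits(cut_point, "cutpoint_result"))
  if (!cut_point$method %in% .screening_methods) {
    stop("screening requires a screening-method cut point, got '",
         cut_point$method, "'", call. = FALSE)
  }
  mean_od > cut_point$cut_point
}

#' Confirmatory-tier call for a sample
#'
#' Computes the percent inhibition between the paired untreated and
#' antigen-inhibited results and confirms the sample when inhibition is
#' strictly above the confirmatory cut point.
#'
#' @param od_untreated,od_inhibited Paired blank-corrected mean ODs.
#' @param cut_point A `"cutpoint_result"` with method
#'   `"confirmatory_linear"`.
#' @return List with `percent_inhibition` and logical `confirmed`.
#' @export
confirm_sample <- function(od_untreated, od_inhibited, cut_point) {
  stopifnot(inherits(cut_point, "cutpoint_result"))
  if (cut_point$method != "confirmatory_linear") {
    stop("confirmation requires a confirmatory cut point, got '",
         cut_point$method, "'", call. = FALSE)
  }
  pi <- percent_inhibition(od_untreated, od_inhibited)
  list(percent_inhibition = pi, confirmed = pi > cut_point$cut_point)
}

#' Endpoint titer from a serial dilution series
#'
#' The reported titer is the highest (most dilute) reciprocal dilution
#' whose OD450 is strictly greater than the blank mean plus 2 blank SDs.
#' If no dilution exceeds the threshold the titer is undetermined
#' (`NA`).
#'
#' @param dilutions Strictly increasing reciprocal dilutions (e.g.
#'   `c(4, 16, 64, 256, 1024)` for a 4-fold series).
#' @param ods Matched OD450 values.
#' @param blank_mean,blank_sd Plate blank summary statistics.
#' @return The reciprocal titer, or `NA` when every dilution fails.
#' @export
determine_titer <- function(dilutions, ods, blank_mean, blank_sd) {
  if (length(dilutions) == 0) stop("empty titration series", call. = FALSE)
  if (length(dilutions) != length(ods)) {
    stop("dilutions and ods must have equal length", call. = FALSE)
  }
  if (any(diff(dilutions) <= 0)) {
    stop("dilutions must be strictly increasing", call. = FALSE)
  }
  threshold <- blank_mean + 2 * blank_sd
  pass <- ods > threshold
  if (!any(pass)) return(NA_real_)
  max(dilutions[pass])
}

#' Two-tier classification of donors for one or both antigens
#'
#' Runs the screen-then-confirm cascade on aggregated sample results:
#' each donor screens on the untreated mean OD against the screening cut
#' point, and screen-positive donors with a paired inhibited result are
#' confirmed on percent inhibition against the confirmatory cut point.
#'
#' @param samples Aggregated sample results ([aggregate_replicates()])
#'   containing conditions `"untreated"` and `"inhibited"` for each
#'   donor x antigen.
#' @param screening_cut A screening `"cutpoint_result"`, or a named list
#'   of them keyed by antigen.
#' @param confirmatory_cut A confirmatory `"cutpoint_result"`, or a
#'   named list keyed by antigen.
#' @param method Label recorded in the output: which screening cut-point
#'   method the classification used (`"with_inhibition"` when the
#'   screening cut point came from immune-inhibited training sera).
#' @return `data.frame` with one row per donor x antigen: `donor_id`,
#'   `antigen`, `method`, `screen_od`, `screen_positive`,
#'   `percent_inhibition`, `confirmed_positive`, `titer`, `isotype`.
#'   `confirmed_positive` is `NA` for screen-negative donors; `titer`
#'   and `isotype` are left `NA` for later annotation.
#' @export
classify_donors <- function(samples, screening_cut, confirmatory_cut,
                            method = c("with_inhibition",
                                       "without_inhibition")) {
  method <- match.arg(method)
  cut_for <- function(cuts, ag) {
    if (inherits(cuts, "cutpoint_result")) return(cuts)
    cuts[[ag]] %||% stop("no cut point supplied for antigen '", ag, "'",
                         call. = FALSE)
  }
  out <- list()
  for (ag in unique(samples$antigen)) {
    s <- samples[samples$antigen == ag, ]
    unt <- s[s$condition == "untreated", ]
    inh <- s[s$condition == "inhibited", ]
    scut <- cut_for(screening_cut, ag)
    ccut <- cut_for(confirmatory_cut, ag)
    screen_pos <- screen_sample(unt$mean_od, scut)
    i <- match(unt$donor_id, inh$donor_id)
    pi <- rep(NA_real_, nrow(unt))
    confirmed <- rep(NA, nrow(unt))
    need <- which(screen_pos)
    if (length(need) > 0) {
      missing_pair <- need[is.na(i[need])]
      if (length(missing_pair) > 0) {
        stop("missing inhibited condition for donor(s): ",
             paste(unt$donor_id[missing_pair], collapse = ", "),
             call. = FALSE)
      }
      cc <- confirm_sample(unt$mean_od[need], inh$mean_od[i[need]], ccut)
      pi[need] <- cc$percent_inhibition
      confirmed[need] <- cc$confirmed
    }
    out[[ag]] <- data.frame(donor_id = unt$donor_id, antigen = ag,
                            method = method, screen_od = unt$mean_od,
                            screen_positive = screen_pos,
                            percent_inhibition = pi,
                            confirmed_positive = confirmed,
                            titer = NA_real_, isotype = NA_character_,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Isotype distribution among confirmed positives
#'
#' Percentage of each IgG subclass among confirmed-positive donors with
#' an isotype call.  IgG4 is always reported, even when absent.
#'
#' @param outcomes Donor outcomes ([classify_donors()]) carrying an
#'   `isotype` column.
#' @param digits Decimal places of the reported percentages.
#' @return Named numeric vector of percentages over IgG1--IgG4 (empty,
#'   with a warning, when no donor has an isotype call).
#' @export
summarize_isotypes <- function(outcomes, digits = 1) {
  conf <- !is.na(outcomes$confirmed_positive) & outcomes$confirmed_positive
  calls <- outcomes$isotype[conf & !is.na(outcomes$isotype)]
  if (length(calls) == 0) {
    warning("no isotyped confirmed-positive donors")
    return(stats::setNames(numeric(0), character(0)))
  }
  lev <- c("IgG1", "IgG2", "IgG3", "IgG4")
  bad <- setdiff(unique(calls), lev)
  if (length(bad) > 0) {
    stop("unknown isotype call(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(calls, levels = lev))
  round_half_up(100 * as.numeric(counts) / length(calls), digits) |>
    stats::setNames(lev)
}
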
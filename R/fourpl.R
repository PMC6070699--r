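#' Four-parameter logistic (4PL) response
#'
#' The immunoassay standard concentration-response model
#' \deqn{OD(c) = L + \frac{U - L}{1 + (EC_{50}/c)^{h}}}
#' with lower asymptote \eqn{L}, upper asymptote \eqn{U}, mid-response
#' concentration \eqn{EC_{50}} and Hill slope \eqn{h}.  With \eqn{h > 0}
#' the response is strictly increasing in concentration; at concentration
#' 0 it equals the lower asymptote.
#'
#' @param conc Concentration(s), ng/mL, >= 0.
#' @param params A [fourpl_params()] list.
#' @return Predicted OD value(s).
#' @export
fourpl <- function(conc, params) {
  stopifnot(all(conc >= 0))
  out <- rep(params$lower_asymptote, length(conc))
  pos <- conc > 0
  out[pos] <- params$lower_asymptote +
    (params$upper_asymptote - params$lower_asymptote) /
    (1 + (params$ec50 / conc[pos])^params$hill_slope)
  out
}

#' @rdname fourpl
#' @param lower_asymptote,upper_asymptote Response plateaus (OD units);
#'   `upper_asymptote` must exceed `lower_asymptote`.
#' @param ec50 Concentration of half-maximal response (ng/mL, > 0).
#' @param hill_slope Hill slope.
#' @export
fourpl_params <- function(lower_asymptote, upper_asymptote, ec50,
                          hill_slope) {
  if (upper_asymptote <= lower_asymptote) {
    stop("upper_asymptote must exceed lower_asymptote", call. = FALSE)
  }
  if (ec50 <= 0) stop("ec50 must be > 0", call. = FALSE)
  structure(list(lower_asymptote = lower_asymptote,
                 upper_asymptote = upper_asymptote,
                 ec50 = ec50, hill_slope = hill_slope),
            class = "fourpl_params")
}

#' @rdname fourpl
#' @param od Observed OD value(s); back-calculation returns `NA` outside
#'   the open asymptote interval.
#' @export
fourpl_inverse <- function(od, params) {
  span <- params$upper_asymptote - params$lower_asymptote
  frac <- (od - params$lower_asymptote) / span
  out <- rep(NA_real_, length(od))
  ok <- !is.na(frac) & frac > 0 & frac < 1
  out[ok] <- params$ec50 * (1 / frac[ok] - 1)^(-1 / params$hill_slope)
  out
}

#' Fit a 4PL standard curve by least squares
#'
#' Fits the four-parameter logistic on untransformed OD against
#' log-spaced concentrations using Levenberg-Marquardt least squares.
#' Starting values come from the response extremes and the mid-response
#' concentration; the EC50 is bounded within the tested concentration
#' range times `[0.01, 100]`.
#'
#' @param standards Sample results of standard wells (e.g. from
#'   [aggregate_replicates()]): a `data.frame` with columns
#'   `spiked_conc`, `mean_od` and optionally `sd_od`.
#' @return An object of class `"fourpl_fit"`: a list with `params`
#'   ([fourpl_params()]), `residual_rms`, `converged`, and the fitted
#'   standards table.
#' @export
fit_4pl <- function(standards) {
  st <- standards[!is.na(standards$spiked_conc) & standards$spiked_conc > 0, ]
  if (length(unique(st$spiked_conc)) < 5) {
    stop("at least 5 distinct standard concentrations are required",
         call. = FALSE)
  }
  st <- st[order(st$spiked_conc), ]
  lo <- min(st$mean_od); hi <- max(st$mean_od)
  mid_od <- (lo + hi) / 2
  lec50_start <- log(st$spiked_conc[which.min(abs(st$mean_od - mid_od))])
  fit <- minpack.lm::nlsLM(
    mean_od ~ lower + (upper - lower) /
      (1 + exp(hill * (lec50 - log(spiked_conc)))),
    data = st,
    start = list(lower = lo, upper = hi, lec50 = lec50_start, hill = 1),
    lower = c(lower = -Inf, upper = -Inf,
              lec50 = log(min(st$spiked_conc) * 0.01), hill = 1e-3),
    upper = c(lower = Inf, upper = Inf,
              lec50 = log(max(st$spiked_conc) * 100), hill = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  params <- fourpl_params(lower_asymptote = unname(cf["lower"]),
                          upper_asymptote = unname(cf["upper"]),
                          ec50 = exp(unname(cf["lec50"])),
                          hill_slope = unname(cf["hill"]))
  structure(list(params = params,
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 converged = fit$convInfo$isConv %||% TRUE,
                 standards = st),
            class = "fourpl_fit")
}

#' Limits of quantitation and assay dynamic range
#'
#' A standard qualifies when its back-calculated concentration recovers
#' the nominal one within `recovery_band` (default 80--120\%) and its
#' replicate coefficient of variation is at most `cv_limit` (default
#' 20\%).  The LLOQ (assay sensitivity) is the lowest qualifying
#' standard and the ULOQ the highest; the dynamic range in OD units is
#' the fitted response span between them.
#'
#' @param standards Standards table with `spiked_conc`, `mean_od`,
#'   `sd_od`.
#' @param fit A [fit_4pl()] object (or its `params`).
#' @param recovery_band Length-2 fraction vector of acceptable
#'   back-calculated recovery.
#' @param cv_limit Maximum replicate CV.
#' @return A list of class `"curve_qc"`: `lloq`, `uloq` (ng/mL, `NA`
#'   when no standard qualifies), `dynamic_range_od`, `residual_rms`,
#'   and the per-standard QC table `qc`.
#' @export
determine_loq <- function(standards, fit, recovery_band = c(0.8, 1.2),
                          cv_limit = 0.2) {
  params <- if (inherits(fit, "fourpl_fit")) fit$params else fit
  st <- standards[!is.na(standards$spiked_conc) & standards$spiked_conc > 0, ]
  st <- st[order(st$spiked_conc), ]
  back <- fourpl_inverse(st$mean_od, params)
  recovery <- back / st$spiked_conc
  cv <- if ("sd_od" %in% names(st)) st$sd_od / st$mean_od else rep(0, nrow(st))
  pass <- !is.na(recovery) &
    recovery >= recovery_band[1] & recovery <= recovery_band[2] &
    cv <= cv_limit
  lloq <- if (any(pass)) min(st$spiked_conc[pass]) else NA_real_
  uloq <- if (any(pass)) max(st$spiked_conc[pass]) else NA_real_
  dr <- if (is.na(lloq)) NA_real_ else
    fourpl(uloq, params) - fourpl(lloq, params)
  if (is.na(lloq)) warning("no standard passed LOQ qualification")
  structure(list(lloq = lloq, uloq = uloq, dynamic_range_od = dr,
                 residual_rms = if (inherits(fit, "fourpl_fit"))
                   fit$residual_rms else NA_real_,
                 qc = data.frame(spiked_conc = st$spiked_conc,
                                 mean_od = st$mean_od,
                                 back_calculated = back,
                                 recovery = recovery, cv = cv,
                                 pass = pass)),
            class = "curve_qc")
}

#' Minimum required serum dilution (MRD)
#'
#' The MRD is the smallest reciprocal serum dilution whose assay dynamic
#' range (OD span between the limits of quantitation) retains at least
#' `retention` (default 80\%) of the dynamic range measured in serum-free
#' assay buffer.
#'
#' @param serum_curves Named list (or named numeric vector) mapping
#'   reciprocal dilution to the dilution's [determine_loq()] result (or
#'   directly to its `dynamic_range_od`).
#' @param buffer_curve The buffer [determine_loq()] result (or its
#'   `dynamic_range_od`).
#' @param retention Required fraction of the buffer dynamic range.
#' @return A list of class `"mrd_result"`: `mrd` (reciprocal dilution,
#'   `NA` when no dilution qualifies), and a `retention` table per
#'   dilution.
#' @export
determine_mrd <- function(serum_curves, buffer_curve, retention = 0.8) {
  dr_of <- function(x) if (inherits(x, "curve_qc")) x$dynamic_range_od
                       else as.numeric(x)
  if (is.numeric(serum_curves)) {
    drs <- as.numeric(serum_curves)
    dils <- as.numeric(names(serum_curves))
  } else {
    drs <- vapply(serum_curves, dr_of, numeric(1))
    dils <- as.numeric(names(serum_curves))
  }
  if (length(dils) < 2) stop("at least 2 dilutions are required",
                             call. = FALSE)
  if (anyNA(dils)) stop("serum_curves must be named by reciprocal dilution",
                        call. = FALSE)
  buffer_dr <- dr_of(buffer_curve)
  ord <- order(dils)
  dils <- dils[ord]; drs <- drs[ord]
  ret <- drs / buffer_dr
  ok <- ret >= retention
  if (any(ok) && !all(diff(ret) >= 0) ) {
    # retention is expected to improve with dilution; a non-monotone
    # profile still yields the smallest qualifying dilution
    warning("retention is not monotone in dilution")
  }
  mrd <- if (any(ok)) dils[which(ok)[1]] else NA_real_
  structure(list(mrd = mrd,
                 retention = data.frame(serum_dilution = dils,
                                        dynamic_range_od = drs,
                                        retention = ret, qualifies = ok),
                 required_retention = retention),
            class = "mrd_result")
}
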
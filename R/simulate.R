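#' Simulation configuration for synthetic ELISA plate data
#'
#' Bundles every parameter of the synthetic OD450 generator: donor
#' demographics and seroprevalence, the log-normal antibody concentration
#' among seropositives, the 4PL concentration-response curve, serum matrix
#' attenuation, competitive-inhibition fractions, seronegative background
#' binding, nuisance factor effects, measurement noise and plate blanks.
#'
#' The defaults describe a drug-naive US donor population screened at a
#' 1:20 serum dilution: seroprevalence 10\% (SaCas9) and 2.5\% (SpCas9),
#' excess free antigen suppressing specific binding by 74.7\% and 87.8\%
#' respectively, and a demographic composition of 17\% African American,
#' 76.5\% Caucasian, 5\% Hispanic, 1.5\% other; 40\% female; age bands
#' 38\%/29\%/25\%/8\% from 19--34 to 65--79 years.
#'
#' @param n_donors Number of donors to simulate.
#' @param prevalence_sa,prevalence_sp Seroprevalence of anti-SaCas9 and
#'   anti-SpCas9 antibodies, as fractions.
#' @param titer_log_mean,titer_log_sd Mean and SD of log antibody
#'   concentration (ng/mL) among seropositive donors.
#' @param fourpl Four-parameter logistic response, a list with
#'   `lower_asymptote`, `upper_asymptote` (OD units), `ec50` (ng/mL) and
#'   `hill_slope`; see [fourpl_params()].
#' @param matrix_k Half-attenuation constant of the serum matrix:
#'   retention at reciprocal dilution `d` is `d / (d + matrix_k)`.  The
#'   default 5 puts 80\% retention exactly at a 1:20 dilution, making
#'   1:20 the minimum required dilution by construction.
#' @param inhibition_fraction_sa,inhibition_fraction_sp Fraction of
#'   specific (antibody-mediated) signal suppressed by pre-incubation
#'   with excess free antigen.
#' @param nonspecific_inhibition Fraction of seronegative background
#'   binding suppressed by excess antigen (default 0.05).
#' @param nonspecific_od_log_mean,nonspecific_od_log_sd Log-normal
#'   parameters of the blank-corrected background OD of seronegative sera.
#' @param nonspecific_log_range Half-width, in units of
#'   `nonspecific_od_log_sd`, at which the background log-normal is
#'   truncated (default 1.3; `Inf` for no truncation).  An ADA-negative
#'   null population excludes samples with extreme specific-like
#'   signal by definition, and the bounded tail keeps the designed 5\%
#'   screening false-positive rate attainable after outlier trimming.
#' @param factor_effects Named list of named numeric vectors giving
#'   multiplicative signal effects per level of `analyst`, `machine`,
#'   `run`, `plate_position`.  `NULL` (default) means all effects 1
#'   (a null design).
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   well noise.
#' @param blank_mean,blank_sd Mean and SD (OD units) of blank wells.
#' @param serum_dilution Reciprocal serum dilution of screening wells.
#' @param demographics Named list of named proportion vectors for `race`,
#'   `gender`, `age`; each must sum to 1.
#' @param streptozyme_rate Population rate of streptozyme (Group A
#'   Streptococcus) positivity, carried as an independent binary donor
#'   covariate.
#' @param seed Optional integer seed applied by the generator functions.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_donors = 200,
                       prevalence_sa = 0.10,
                       prevalence_sp = 0.025,
                       titer_log_mean = log(200),
                       titer_log_sd = 1,
                       fourpl = fourpl_params(0.05, 3.0, 30, 1),
                       matrix_k = 5,
                       inhibition_fraction_sa = 0.747,
                       inhibition_fraction_sp = 0.878,
                       nonspecific_inhibition = 0.05,
                       nonspecific_od_log_mean = log(0.35),
                       nonspecific_od_log_sd = 0.35,
                       nonspecific_log_range = 1.3,
                       factor_effects = NULL,
                       noise_cv = 0.05,
                       blank_mean = 0.05,
                       blank_sd = 0.005,
                       serum_dilution = 20,
                       demographics = default_demographics(),
                       streptozyme_rate = 0.58,
                       seed = NULL) {
  check_count(n_donors, "n_donors")
  check_fraction(prevalence_sa, "prevalence_sa")
  check_fraction(prevalence_sp, "prevalence_sp")
  check_fraction(inhibition_fraction_sa, "inhibition_fraction_sa")
  check_fraction(inhibition_fraction_sp, "inhibition_fraction_sp")
  check_fraction(nonspecific_inhibition, "nonspecific_inhibition")
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (matrix_k < 0) stop("matrix_k must be >= 0", call. = FALSE)
  for (axis in names(demographics)) {
    p <- demographics[[axis]]
    if (abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("demographic proportions for '%s' must sum to 1", axis),
           call. = FALSE)
    }
  }
  cfg <- list(n_donors = as.integer(n_donors),
              prevalence_sa = prevalence_sa, prevalence_sp = prevalence_sp,
              titer_log_mean = titer_log_mean, titer_log_sd = titer_log_sd,
              fourpl = fourpl, matrix_k = matrix_k,
              inhibition_fraction_sa = inhibition_fraction_sa,
              inhibition_fraction_sp = inhibition_fraction_sp,
              nonspecific_inhibition = nonspecific_inhibition,
              nonspecific_od_log_mean = nonspecific_od_log_mean,
              nonspecific_od_log_sd = nonspecific_od_log_sd,
              nonspecific_log_range = nonspecific_log_range,
              factor_effects = factor_effects,
              noise_cv = noise_cv,
              blank_mean = blank_mean, blank_sd = blank_sd,
              serum_dilution = as.integer(serum_dilution),
              demographics = demographics,
              streptozyme_rate = streptozyme_rate,
              seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_demographics <- function() {
  list(race = c("African American" = 0.17, "Caucasian" = 0.765,
                "Hispanic" = 0.05, "Other" = 0.015),
       gender = c("Female" = 0.40, "Male" = 0.60),
       age = c("19-34" = 0.38, "35-49" = 0.29,
               "50-64" = 0.25, "65-79" = 0.08))
}

#' Serum matrix signal retention at a given dilution
#'
#' Saturating retention curve `r(d) = d / (d + k)`: concentrated serum
#' (small reciprocal dilution `d`) attenuates the assay signal most, and
#' retention approaches 1 as the serum is diluted out.
#'
#' @param dilution Reciprocal serum dilution(s), >= 1.
#' @param k Half-attenuation constant (see [sim_config()]).
#' @return Retention fraction(s) in (0, 1].
#' @export
matrix_retention <- function(dilution, k) {
  stopifnot(all(dilution >= 1))
  dilution / (dilution + k)
}

# Truncated log-normal background draws: the log is normal restricted
# to +/- range standard deviations.
rbackground <- function(n, config) {
  m <- config$nonspecific_od_log_mean
  s <- config$nonspecific_od_log_sd
  r <- config$nonspecific_log_range %||% Inf
  if (!is.finite(r)) return(stats::rlnorm(n, m, s))
  u <- stats::runif(n, stats::pnorm(-r), stats::pnorm(r))
  exp(m + s * stats::qnorm(u))
}

# Log-normal multiplicative noise with unit mean and coefficient of
# variation cv; a vector of 1s when cv == 0.
rnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a donor population with known serostatus
#'
#' Assigns demographic strata by the configured proportions, draws
#' serostatus per antigen as independent Bernoulli variables at the
#' configured prevalences, and draws true antibody concentrations
#' (ng/mL) log-normally among seropositives.  Seronegative donors have
#' true concentration exactly 0.
#'
#' @param config A [sim_config()].
#' @return `data.frame` with one row per donor: `donor_id`, `race`,
#'   `gender`, `age_band`, `seropositive_sa`, `seropositive_sp`,
#'   `true_conc_sa`, `true_conc_sp`, `streptozyme_positive`.
#' @export
generate_donors <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_donors
  dg <- config$demographics
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  pos_sa <- stats::rbinom(n, 1, config$prevalence_sa) == 1
  pos_sp <- stats::rbinom(n, 1, config$prevalence_sp) == 1
  conc <- function(pos) {
    x <- numeric(n)
    x[pos] <- stats::rlnorm(sum(pos), config$titer_log_mean,
                            config$titer_log_sd)
    x
  }
  data.frame(donor_id = sprintf("D%04d", seq_len(n)),
             race = draw(dg$race),
             gender = draw(dg$gender),
             age_band = draw(dg$age),
             seropositive_sa = pos_sa,
             seropositive_sp = pos_sp,
             true_conc_sa = conc(pos_sa),
             true_conc_sp = conc(pos_sp),
             streptozyme_positive =
               stats::rbinom(n, 1, config$streptozyme_rate) == 1,
             stringsAsFactors = FALSE)
}

# Multiplicative nuisance effect for one well given its factor levels.
factor_effect <- function(config, analyst, machine, run, position) {
  fe <- config$factor_effects
  if (is.null(fe)) return(rep(1, length(analyst)))
  get <- function(name, level) {
    v <- fe[[name]]
    if (is.null(v)) return(rep(1, length(level)))
    out <- v[level]
    out[is.na(out)] <- 1
    unname(out)
  }
  get("analyst", analyst) * get("machine", machine) *
    get("run", run) * get("plate_position", position)
}

#' Simulate screening/confirmatory plate measurements for a donor set
#'
#' Emits one well per donor x antigen x condition x replicate at the
#' configured serum dilution, plus quadruplicate blank wells per plate.
#' The OD model is: a blank draw, plus the donor signal scaled by
#' nuisance factor effects and multiplicative log-normal noise.  The
#' donor signal is the 4PL response at the true concentration,
#' multiplied by the serum matrix retention [matrix_retention()] at the
#' assay dilution, for seropositives; or a log-normal background draw
#' for seronegatives (drawn once per donor x antigen and shared across
#' conditions and replicates; the background distribution is defined at
#' the assay dilution and is not further attenuated).  Pre-incubation
#' with excess antigen
#' (condition `"inhibited"`) multiplies the specific signal by
#' `1 - inhibition_fraction` and the nonspecific background by
#' `1 - nonspecific_inhibition`.
#'
#' @param donors Output of [generate_donors()].
#' @param config A [sim_config()].
#' @param antigens Antigens to assay (default both).
#' @param conditions Conditions to emit (default untreated + inhibited).
#' @param n_replicates Wells per donor x antigen x condition (default 3).
#' @param donors_per_plate Donors accommodated on one 96-well plate.
#' @return A validated plate table (see [plate_columns()]).
#' @export
generate_measurements <- function(donors, config,
                                  antigens = c("SaCas9", "SpCas9"),
                                  conditions = c("untreated", "inhibited"),
                                  n_replicates = 3,
                                  donors_per_plate = 15) {
  stopifnot(inherits(config, "sim_config"), nrow(donors) > 0)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  n <- nrow(donors)
  d <- config$serum_dilution
  ret <- matrix_retention(d, config$matrix_k)

  plate_of <- ceiling(seq_len(n) / donors_per_plate)
  run_id <- sprintf("plate%02d", plate_of)
  analyst <- ifelse(plate_of %% 2 == 1, "A1", "A2")
  machine <- ifelse(((plate_of - 1) %/% 2) %% 2 == 0, "M1", "M2")
  position <- sprintf("Q%d", (seq_len(n) - 1) %% 4 + 1)

  rows <- list()
  for (ag in antigens) {
    pos <- donors[[if (ag == "SaCas9") "seropositive_sa" else "seropositive_sp"]]
    conc <- donors[[if (ag == "SaCas9") "true_conc_sa" else "true_conc_sp"]]
    inh_frac <- if (ag == "SaCas9") config$inhibition_fraction_sa
                else config$inhibition_fraction_sp
    # one signal per donor, shared by replicates and both conditions
    signal <- ifelse(pos,
                     ret * fourpl(conc, config$fourpl),
                     rbackground(n, config))
    for (cond in conditions) {
      mult <- if (cond == "inhibited") {
        ifelse(pos, 1 - inh_frac, 1 - config$nonspecific_inhibition)
      } else rep(1, n)
      for (r in seq_len(n_replicates)) {
        od <- stats::rnorm(n, config$blank_mean, config$blank_sd) +
          signal * mult *
          factor_effect(config, analyst, machine, run_id, position) *
          rnoise(n, config$noise_cv)
        rows[[length(rows) + 1]] <- data.frame(
          donor_id = donors$donor_id, antigen = ag, condition = cond,
          spiked_conc = NA_real_, serum_dilution = d,
          replicate = r, analyst = analyst, machine = machine,
          run = run_id, plate_position = position, od450 = od,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- rbind(out, blank_wells(unique(run_id), config,
                                analyst = analyst[!duplicated(run_id)],
                                machine = machine[!duplicated(run_id)]))
  rownames(out) <- NULL
  validate_plate_table(out)
  out
}

# Quadruplicate blank wells for each named plate.
blank_wells <- function(runs, config, analyst = "A1", machine = "M1") {
  n <- length(runs)
  analyst <- rep_len(analyst, n)
  machine <- rep_len(machine, n)
  do.call(rbind, lapply(seq_along(runs), function(i) {
    data.frame(donor_id = "", antigen = "", condition = "blank",
               spiked_conc = NA_real_, serum_dilution = NA_integer_,
               replicate = 1:4, analyst = analyst[i], machine = machine[i],
               run = runs[i], plate_position = "B",
               od450 = pmax(stats::rnorm(4, config$blank_mean,
                                         config$blank_sd), 0),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a spiked standard-curve dilution series
#'
#' Standards at `top_conc / fold^k`, `k = 0 .. n_points - 1`, each in
#' `n_replicates` wells, with ODs drawn from the configured 4PL response
#' plus blank and multiplicative noise.  A 7-point 4-fold series from
#' 3000 ng/mL ends at 0.73 ng/mL; from 1000 ng/mL it ends at 0.24 ng/mL.
#'
#' @param config A [sim_config()].
#' @param top_conc Highest standard concentration (ng/mL).
#' @param fold Dilution factor between successive points (> 1).
#' @param n_points Number of standards (>= 2).
#' @param n_replicates Wells per standard (default 3).
#' @param antigen Antigen label for the emitted wells.
#' @param dilution Optional reciprocal serum dilution: when given, the
#'   4PL signal is multiplied by the matrix retention
#'   [matrix_retention()] at that dilution; `NA` (default) means
#'   serum-free assay buffer (retention 1).
#' @return A plate table of `condition == "standard"` wells plus
#'   quadruplicate blanks.
#' @export
generate_standard_series <- function(config, top_conc, fold, n_points,
                                     n_replicates = 3, antigen = "SaCas9",
                                     dilution = NA) {
  stopifnot(inherits(config, "sim_config"), top_conc > 0)
  if (fold <= 1) stop("fold must be > 1", call. = FALSE)
  check_count(n_points, "n_points", min = 2L)
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  conc <- standard_concentrations(top_conc, fold, n_points)
  ret <- if (is.na(dilution)) 1 else matrix_retention(dilution,
                                                      config$matrix_k)
  rows <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(donor_id = "", antigen = antigen, condition = "standard",
               spiked_conc = conc,
               serum_dilution = if (is.na(dilution)) NA_integer_
                                else as.integer(dilution),
               replicate = r, analyst = "A1", machine = "M1",
               run = "std01", plate_position = "S",
               od450 = stats::rnorm(n_points, config$blank_mean,
                                    config$blank_sd) +
                 ret * fourpl(conc, config$fourpl) * rnoise(n_points,
                                                            config$noise_cv),
               stringsAsFactors = FALSE)
  }))
  out <- rbind(rows, blank_wells("std01", config))
  rownames(out) <- NULL
  validate_plate_table(out)
  out
}

#' @rdname generate_standard_series
#' @export
standard_concentrations <- function(top_conc, fold, n_points) {
  if (fold <= 1) stop("fold must be > 1", call. = FALSE)
  top_conc / fold^(seq_len(n_points) - 1)
}

#' Draw blank-corrected background ODs of seronegative sera
#'
#' Samples from the generator's seronegative background distribution
#' (truncated log-normal), optionally under the inhibited condition
#' (background scaled by `1 - nonspecific_inhibition`) and with well
#' noise applied.  This is the null distribution used to calibrate
#' screening cut points.
#'
#' @param n Number of draws.
#' @param config A [sim_config()].
#' @param condition `"untreated"` or `"inhibited"`.
#' @return Numeric vector of blank-corrected mean ODs.
#' @export
draw_negative_ods <- function(n, config, condition = "untreated") {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition, c("untreated", "inhibited"))
  mult <- if (condition == "inhibited") 1 - config$nonspecific_inhibition
          else 1
  rbackground(n, config) * mult * rnoise(n, config$noise_cv)
}

#' Simulate the balanced precision-assessment panel
#'
#' Crossed design for assay-precision evaluation: `n_samples` drug-naive
#' sera, each measured in `n_replicates` wells under every analyst x
#' machine combination, with one run per combination.  Plate positions
#' rotate Latin-square style across runs, so every sample is measured at
#' every position (each sample x position cell holds `n_replicates`
#' wells) and the position factor is crossed with sample rather than
#' aliased to it.  The default 48 samples x 3 replicates x 2 analysts x
#' 2 machines gives 576 measurements.
#'
#' @param config A [sim_config()].
#' @param n_samples Number of serum samples (default 48).
#' @param n_replicates Replicates per sample per condition (default 3).
#' @param analysts,machines Level labels for the two crossed factors.
#' @param n_positions Number of plate-position levels cycled across
#'   samples (default 4).
#' @return A plate table (no blank wells; ODs are already on the
#'   blank-corrected scale used by the precision analysis).
#' @export
generate_precision_panel <- function(config, n_samples = 48,
                                     n_replicates = 3,
                                     analysts = c("A1", "A2"),
                                     machines = c("M1", "M2"),
                                     n_positions = 4) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 3L)
  sample_id <- sprintf("S%02d", seq_len(n_samples))
  bg <- rbackground(n_samples, config)
  grid <- expand.grid(sample = seq_len(n_samples),
                      analyst = analysts, machine = machines,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  grid$run <- paste0("run_", grid$analyst, "_", grid$machine)
  run_idx <- as.integer(factor(grid$run))
  grid$position <- sprintf("P%d", (grid$sample + run_idx - 2) %%
                             n_positions + 1)
  eff <- factor_effect(config, grid$analyst, grid$machine, grid$run,
                       grid$position)
  od <- bg[grid$sample] * eff * rnoise(nrow(grid), config$noise_cv)
  out <- data.frame(donor_id = sample_id[grid$sample], antigen = "SaCas9",
                    condition = "untreated", spiked_conc = NA_real_,
                    serum_dilution = config$serum_dilution,
                    replicate = grid$replicate, analyst = grid$analyst,
                    machine = grid$machine, run = grid$run,
                    plate_position = grid$position, od450 = od,
                    stringsAsFactors = FALSE)
  validate_plate_table(out)
  out
}
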
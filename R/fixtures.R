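#' Synthetic 200-donor survey fixture
#'
#' A synthetic per-donor reconstruction of a 200-donor anti-Cas9
#' seroprevalence survey, shipped as
#' `extdata/synthetic_survey_donors.csv`.  The per-donor rows are
#' synthetic -- no per-donor assignments were ever published -- but they
#' are constructed so that every demographic marginal (race, gender, age
#' band), every stratum-level screening and confirmed count under both
#' cut-point methods, and the titer distribution among confirmed
#' positives agree with the published summary tables.  Tier nesting
#' holds by construction: confirmed implies screen-positive, and every
#' donor positive under the untreated-serum (higher) cut point is also
#' positive under the immune-inhibition (lower) cut point.
#'
#' @return A list with two data.frames: `demographics` (one row per
#'   donor: `donor_id`, `race`, `gender`, `age_band`) and `outcomes`
#'   (one row per donor x antigen x method: `donor_id`, `antigen`,
#'   `method`, `screen_positive`, `confirmed_positive`, `titer`,
#'   `isotype`).  `confirmed_positive` is `NA` on screen-negative rows;
#'   titers and isotype calls are attached to the with-inhibition rows,
#'   where confirmation determined eligibility for titration.
#' @export
ada_survey_fixture <- function() {
  path <- system.file("extdata", "synthetic_survey_donors.csv",
                      package = "adatier", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  demographics <- raw[, c("donor_id", "race", "gender", "age_band")]
  long_rows <- function(ag, key) {
    do.call(rbind, lapply(c("without_inhibition", "with_inhibition"),
                          function(meth) {
      suffix <- if (meth == "with_inhibition") "with" else "without"
      screen <- raw[[paste0(key, "_screen_", suffix)]]
      conf <- raw[[paste0(key, "_confirmed_", suffix)]]
      with_m <- meth == "with_inhibition"
      data.frame(donor_id = raw$donor_id, antigen = ag, method = meth,
                 screen_positive = screen,
                 confirmed_positive = ifelse(screen, conf, NA),
                 titer = if (with_m) raw[[paste0(key, "_titer")]]
                         else NA_integer_,
                 isotype = if (with_m) {
                   ifelse(raw[[paste0(key, "_isotype")]] == "",
                          NA_character_, raw[[paste0(key, "_isotype")]])
                 } else NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }
  outcomes <- rbind(long_rows("SaCas9", "sa"), long_rows("SpCas9", "sp"))
  rownames(outcomes) <- NULL
  list(demographics = demographics, outcomes = outcomes)
}
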
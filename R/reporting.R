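#' Stratified seroprevalence table
#'
#' Counts and percentages of screening-positive and confirmed-positive
#' donors per demographic stratum (race, gender, age band, and a total
#' row), per antigen, and per cut-point method (without or with immune
#' inhibition).  Percentages are 100 x count / stratum size, rounded
#' half-up to one decimal.  Stratum counts are checked to sum to the
#' total row along every axis.
#'
#' @param outcomes Donor outcomes (see [classify_donors()]): columns
#'   `donor_id`, `antigen`, `method`, `screen_positive`,
#'   `confirmed_positive`; one row per donor x antigen x method.
#' @param demographics One row per donor: `donor_id`, `race`, `gender`,
#'   `age_band`.
#' @return `data.frame` of class `"prevalence_table"` with columns
#'   `axis`, `stratum`, `n_stratum`, `antigen`, `method`, `tier`,
#'   `count`, `percent`, and attribute `n_total`.
#' @export
prevalence_table <- function(outcomes, demographics) {
  idx <- match(outcomes$donor_id, demographics$donor_id)
  if (anyNA(idx)) {
    stop("no demographics for donor(s): ",
         paste(unique(outcomes$donor_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  o <- outcomes
  o$race <- demographics$race[idx]
  o$gender <- demographics$gender[idx]
  o$age_band <- demographics$age_band[idx]
  n_total <- length(unique(demographics$donor_id))

  axes <- list(race = "race", gender = "gender", age = "age_band",
               total = NULL)
  rows <- list()
  for (ag in unique(o$antigen)) {
    for (meth in unique(o$method)) {
      sub <- o[o$antigen == ag & o$method == meth, ]
      for (axis in names(axes)) {
        col <- axes[[axis]]
        strata <- if (is.null(col)) list(Total = sub) else
          split(sub, sub[[col]])
        for (sname in names(strata)) {
          s <- strata[[sname]]
          n_str <- if (is.null(col)) n_total else
            sum(demographics[[col]] == sname)
          scr <- sum(s$screen_positive, na.rm = TRUE)
          conf <- sum(s$confirmed_positive, na.rm = TRUE)
          for (tier in c("screening", "confirmed")) {
            cnt <- if (tier == "screening") scr else conf
            rows[[length(rows) + 1]] <- data.frame(
              axis = axis, stratum = sname, n_stratum = n_str,
              antigen = ag, method = meth, tier = tier, count = cnt,
              percent = round_half_up(100 * cnt / n_str, 1),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # axis-sum consistency: strata must add up to the total row
  tot <- tab[tab$axis == "total", ]
  for (axis in c("race", "gender", "age")) {
    a <- tab[tab$axis == axis, ]
    sums <- stats::aggregate(count ~ antigen + method + tier, a, sum)
    chk <- merge(sums, tot, by = c("antigen", "method", "tier"))
    if (any(chk$count.x != chk$count.y)) {
      stop("internal error: stratum counts along axis '", axis,
           "' do not sum to the total row", call. = FALSE)
    }
    nsum <- sum(a$n_stratum[a$antigen == a$antigen[1] &
                              a$method == a$method[1] &
                              a$tier == "screening"])
    if (nsum != n_total) {
      stop("internal error: stratum sizes along axis '", axis,
           "' do not sum to the donor total", call. = FALSE)
    }
  }
  structure(tab, class = c("prevalence_table", "data.frame"),
            n_total = n_total)
}

#' Titer distribution among confirmed positives
#'
#' @param outcomes Donor outcomes with a `titer` column (reciprocal
#'   dilution; `NA` for untitrated donors).  Titers may only be present
#'   on confirmed-positive rows.
#' @return `data.frame` with columns `antigen`, `titer`, `count`, plus
#'   attribute `n_titrated` (the grand total of titrated donors).
#' @export
titer_table <- function(outcomes) {
  t_rows <- outcomes[!is.na(outcomes$titer), , drop = FALSE]
  if (nrow(t_rows) > 0 &&
      any(is.na(t_rows$confirmed_positive) | !t_rows$confirmed_positive)) {
    stop("titers are only defined for confirmed-positive donors",
         call. = FALSE)
  }
  if (nrow(t_rows) == 0) {
    out <- data.frame(antigen = character(), titer = numeric(),
                      count = integer())
    return(structure(out, n_titrated = 0L))
  }
  agg <- stats::aggregate(list(count = t_rows$titer),
                          by = list(antigen = t_rows$antigen,
                                    titer = t_rows$titer),
                          FUN = length)
  agg <- agg[order(agg$antigen, -agg$titer), ]
  rownames(agg) <- NULL
  structure(agg, n_titrated = nrow(t_rows))
}

#' Demographic composition table
#'
#' One row per demographic stratum with count and percentage of the
#' donor population, plus a total row.
#'
#' @param demographics One row per donor: `donor_id`, `race`, `gender`,
#'   `age_band`.
#' @return `data.frame` with columns `axis`, `stratum`, `count`,
#'   `percent`.
#' @export
demographics_table <- function(demographics) {
  n <- nrow(demographics)
  rows <- list()
  for (axis in c("race", "gender", "age_band")) {
    tab <- table(demographics[[axis]])
    for (i in seq_along(tab)) {
      rows[[length(rows) + 1]] <- data.frame(
        axis = axis, stratum = names(tab)[i],
        count = as.integer(tab[[i]]),
        percent = round_half_up(100 * tab[[i]] / n, 1),
        stringsAsFactors = FALSE)
    }
  }
  rows[[length(rows) + 1]] <- data.frame(axis = "total", stratum = "Total",
                                         count = n, percent = 100,
                                         stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.prevalence_table <- function(x, ...) {
  n <- attr(x, "n_total") %||% max(x$n_stratum)
  cat("Stratified ADA prevalence (n =", n, "donors)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
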
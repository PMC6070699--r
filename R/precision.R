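#' Verify the balance of a precision-assessment design
#'
#' The precision study requires a balanced design: every sample measured
#' the same number of times under every level of each crossed factor,
#' and every factor level carrying the same total number of wells.  For
#' the reference design of 48 samples x 3 replicates x 2 analysts x
#' 2 machines this gives 576 measurements.
#'
#' @param measurements Plate table (blank wells are ignored).
#' @param crossed Factors crossed with samples (each sample is measured
#'   equally often at every level).
#' @param nested Factors whose levels must carry equal total well counts
#'   but are not crossed within sample.
#' @return A list of class `"balance_report"`: `balanced` (logical),
#'   `total_measurements`, and a `deficient` data.frame naming every
#'   unbalanced cell (`factor`, `level`, `donor_id`, `count`,
#'   `expected`).
#' @export
check_balance <- function(measurements,
                          crossed = c("analyst", "machine", "run",
                                      "plate_position"),
                          nested = character(0)) {
  m <- measurements[measurements$condition != "blank", , drop = FALSE]
  if (nrow(m) == 0) stop("no measurements to check", call. = FALSE)
  deficient <- list()
  flag <- function(factor, level, donor, count, expected) {
    deficient[[length(deficient) + 1]] <<-
      data.frame(factor = factor, level = level, donor_id = donor,
                 count = count, expected = expected,
                 stringsAsFactors = FALSE)
  }
  for (f in crossed) {
    tab <- table(m$donor_id, m[[f]])
    expected <- max(tab)
    bad <- which(tab != expected, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      for (i in seq_len(nrow(bad))) {
        flag(f, colnames(tab)[bad[i, 2]], rownames(tab)[bad[i, 1]],
             tab[bad[i, 1], bad[i, 2]], expected)
      }
    }
  }
  for (f in nested) {
    tab <- table(m[[f]])
    expected <- max(tab)
    bad <- which(tab != expected)
    for (i in bad) flag(f, names(tab)[i], NA_character_, tab[[i]], expected)
  }
  deficient <- if (length(deficient) > 0) do.call(rbind, deficient) else
    data.frame(factor = character(), level = character(),
               donor_id = character(), count = integer(),
               expected = integer())
  structure(list(balanced = nrow(deficient) == 0,
                 total_measurements = nrow(m),
                 deficient = deficient),
            class = "balance_report")
}

#' Assay precision tests and the fixed/floating cut-point decision
#'
#' For each nuisance factor (analyst, machine, run, plate position) the
#' OD measurements are tested for equality of means by one-way ANOVA and
#' for homogeneity of variance by Levene's test (Brown-Forsythe variant,
#' deviations from the group median).  The sample term is tested by
#' one-way ANOVA with the serum sample as the grouping factor.  When
#' every factor shows no significant mean or variance difference
#' (all p > `alpha`), a single fixed cut point is justified; otherwise a
#' floating (run-normalized) cut point is indicated.
#'
#' @param measurements Plate table of the precision panel (blank wells
#'   ignored).
#' @param alpha Significance level for the homogeneity gates (default
#'   0.05).
#' @param factors Factor columns to test.
#' @return A list of class `"precision_report"`: `anova_p` and
#'   `levene_p` (named per factor), `sample_p`, `decision` (`"fixed"` or
#'   `"floating"`), `alpha`, and `skipped` (factors with fewer than two
#'   levels).
#' @export
precision_tests <- function(measurements, alpha = 0.05,
                            factors = c("analyst", "machine", "run",
                                        "plate_position")) {
  m <- measurements[measurements$condition != "blank", , drop = FALSE]
  if (nrow(m) == 0) stop("no measurements to test", call. = FALSE)
  if (stats::sd(m$od450) == 0) {
    stop("degenerate input: all OD values identical; variance tests are ",
         "undefined", call. = FALSE)
  }
  anova_p <- levene_p <- stats::setNames(numeric(0), character(0))
  skipped <- character(0)
  for (f in factors) {
    g <- factor(m[[f]])
    if (nlevels(g) < 2) {
      warning("factor '", f, "' has a single level; skipped")
      skipped <- c(skipped, f)
      next
    }
    anova_p[f] <- stats::anova(stats::lm(m$od450 ~ g))[["Pr(>F)"]][1]
    levene_p[f] <- car::leveneTest(m$od450, g,
                                   center = stats::median)[1, "Pr(>F)"]
  }
  sample_p <- {
    g <- factor(m$donor_id)
    if (nlevels(g) < 2) NA_real_
    else stats::anova(stats::lm(m$od450 ~ g))[["Pr(>F)"]][1]
  }
  decision <- if (length(anova_p) > 0 &&
                  all(anova_p > alpha) && all(levene_p > alpha)) "fixed"
              else "floating"
  structure(list(anova_p = anova_p, levene_p = levene_p,
                 sample_p = sample_p, decision = decision, alpha = alpha,
                 skipped = skipped),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("Assay precision report (alpha =", x$alpha, ")\n")
  tab <- data.frame(factor = names(x$anova_p),
                    anova_p = signif(unname(x$anova_p), 4),
                    levene_p = signif(unname(x$levene_p), 4))
  print(tab, row.names = FALSE)
  cat("sample-term ANOVA p:",
      format.pval(x$sample_p, digits = 3, eps = 1e-3), "\n")
  cat("cut-point decision:", x$decision, "\n")
  invisible(x)
}
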
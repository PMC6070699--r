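make_cut <- function(value, method) {
  adatier:::new_cutpoint_result(value, method, 48L, 0L)
}

test_that("screening uses a strict greater-than rule", {
  cut <- make_cut(1.012, "parametric_log")
  expect_true(screen_sample(1.10, cut))
  expect_false(screen_sample(1.012, cut))
  expect_false(screen_sample(0.2, make_cut(0.5129, "nonparametric_p95")))
  expect_error(screen_sample(1, make_cut(70, "confirmatory_linear")),
               "screening")
})

test_that("confirmation compares percent inhibition strictly to its cut point", {
  ccut <- make_cut(71.61, "confirmatory_linear")
  res <- confirm_sample(1.0, 0.2, ccut)         # 80% inhibition
  expect_equal(res$percent_inhibition, 80)
  expect_true(res$confirmed)
  exact <- confirm_sample(1.0, 1.0 - 0.7161, ccut)
  expect_equal(exact$percent_inhibition, 71.61)
  expect_false(exact$confirmed)
  neg <- confirm_sample(1.0, 1.05, ccut)
  expect_false(neg$confirmed)
  expect_error(confirm_sample(1, 0.5, make_cut(1, "parametric_log")),
               "confirmatory")
})

test_that("endpoint titer is the highest dilution above blank + 2 SD", {
  dil <- c(4, 16, 64, 256, 1024)
  ods <- c(2.0, 1.2, 0.4, 0.09, 0.06)
  expect_equal(determine_titer(dil, ods, 0.05, 0.01), 256)   # threshold 0.07
  expect_true(is.na(determine_titer(dil, rep(0.01, 5), 0.05, 0.01)))
  # a value exactly at the threshold is excluded by the strict rule
  expect_equal(determine_titer(dil, c(2, 1, 0.5, 0.07, 0.01), 0.05, 0.01),
               64)
  expect_error(determine_titer(numeric(0), numeric(0), 0.05, 0.01),
               "empty")
  expect_error(determine_titer(c(4, 4, 16), c(1, 1, 1), 0.05, 0.01),
               "increasing")
  # titer never increases as the blank threshold rises
  thresholds <- seq(0, 2.2, by = 0.05)
  titers <- vapply(thresholds, function(th) {
    t <- determine_titer(dil, ods, th, 0)
    if (is.na(t)) 0 else t
  }, numeric(1))
  expect_true(all(diff(titers) <= 0))
})

test_that("isotype summary covers IgG1-IgG4 with a zero for absent classes", {
  out <- data.frame(donor_id = c("a", "b", "c"), antigen = "SaCas9",
                    method = "with_inhibition",
                    screen_positive = TRUE, confirmed_positive = TRUE,
                    titer = NA_real_,
                    isotype = c("IgG1", "IgG2", "IgG3"))
  s <- summarize_isotypes(out)
  expect_equal(unname(s), c(33.3, 33.3, 33.3, 0))
  out$isotype <- "IgG1"
  expect_equal(unname(summarize_isotypes(out)), c(100, 0, 0, 0))
  out$isotype <- NA_character_
  expect_warning(empty <- summarize_isotypes(out), "no isotyped")
  expect_length(empty, 0)
})

test_that("the cascade is monotone in the untreated OD", {
  scut <- make_cut(0.6, "nonparametric_p95")
  ods <- seq(0.1, 2, by = 0.01)
  calls <- screen_sample(ods, scut)
  expect_true(all(diff(calls) >= 0))   # raising OD never un-screens
})

test_that("noise-free generator output classifies deterministically", {
  cfg <- sim_config(n_donors = 60, prevalence_sa = 0.3, noise_cv = 0,
                    blank_sd = 0, seed = 201)
  don <- generate_donors(cfg)
  pm <- generate_measurements(don, cfg, antigens = "SaCas9")
  agg <- aggregate_replicates(subtract_blank(pm, blank_summary(pm)))
  scut <- make_cut(0.62, "nonparametric_p95")
  ccut <- make_cut(20, "confirmatory_linear")
  out <- classify_donors(agg, scut, ccut, method = "with_inhibition")
  pos <- don$seropositive_sa[match(out$donor_id, don$donor_id)]
  above <- out$screen_od > 0.62
  # every seropositive above the cut point confirms, because the 74.7%
  # inhibition fraction exceeds the confirmatory cut point
  expect_true(all(out$confirmed_positive[pos & above]))
  expect_equal(out$percent_inhibition[pos & above],
               rep(74.7, sum(pos & above)), tolerance = 1e-9)
  # screen-negative donors carry no confirmatory call
  expect_true(all(is.na(out$confirmed_positive[!above])))
})

test_that("classify_donors enforces paired conditions and antigen cut maps", {
  cfg <- sim_config(n_donors = 10, prevalence_sa = 1, seed = 202)
  don <- generate_donors(cfg)
  pm <- generate_measurements(don, cfg, antigens = "SaCas9")
  agg <- aggregate_replicates(subtract_blank(pm, blank_summary(pm)))
  no_inh <- agg[agg$condition == "untreated", ]
  expect_error(classify_donors(no_inh, make_cut(0.1, "nonparametric_p95"),
                               make_cut(20, "confirmatory_linear")),
               "missing inhibited")
  both <- classify_donors(
    agg,
    list(SaCas9 = make_cut(0.1, "nonparametric_p95")),
    list(SaCas9 = make_cut(20, "confirmatory_linear")))
  expect_equal(nrow(both), 10)
})
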
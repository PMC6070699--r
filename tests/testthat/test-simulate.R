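test_that("donor generation honours strata, prevalence bounds and seeds", {
  cfg <- sim_config(n_donors = 200, seed = 123)
  don <- generate_donors(cfg)
  expect_equal(nrow(don), 200)
  # stratum counts within multinomial sampling error of 34/153/10/3
  counts <- table(factor(don$race, names(default_demographics()$race)))
  expected <- 200 * default_demographics()$race
  tol <- 4 * sqrt(expected * (1 - default_demographics()$race))
  expect_true(all(abs(counts - expected) <= pmax(tol, 6)))
  # fixed seed reproduces bit-identically
  expect_identical(don, generate_donors(cfg))

  cfg0 <- sim_config(n_donors = 50, prevalence_sa = 0, seed = 1)
  d0 <- generate_donors(cfg0)
  expect_false(any(d0$seropositive_sa))
  expect_true(all(d0$true_conc_sa == 0))

  cfg1 <- sim_config(n_donors = 1000, prevalence_sa = 1, seed = 1)
  expect_equal(mean(generate_donors(cfg1)$seropositive_sa), 1)

  bad_dg <- default_demographics()
  bad_dg$race[1] <- bad_dg$race[1] + 0.01
  expect_error(sim_config(demographics = bad_dg), "sum to 1")
})

test_that("noise-free ODs are exact 4PL evaluations plus blank", {
  cfg <- sim_config(n_donors = 30, prevalence_sa = 0.5, noise_cv = 0,
                    blank_sd = 0, seed = 5)
  don <- generate_donors(cfg)
  pm <- generate_measurements(don, cfg, antigens = "SaCas9",
                              conditions = "untreated")
  pm <- pm[pm$condition == "untreated", ]
  pos <- don$seropositive_sa[match(pm$donor_id, don$donor_id)]
  conc <- don$true_conc_sa[match(pm$donor_id, don$donor_id)]
  r <- matrix_retention(cfg$serum_dilution, cfg$matrix_k)
  expected <- cfg$blank_mean + r * fourpl(conc, cfg$fourpl)
  expect_equal(pm$od450[pos], expected[pos], tolerance = 1e-12)
})

test_that("inhibited condition suppresses signal by the configured fraction", {
  cfg <- sim_config(n_donors = 40, prevalence_sa = 0.5, noise_cv = 0,
                    blank_sd = 0, seed = 9)
  don <- generate_donors(cfg)
  pm <- generate_measurements(don, cfg, antigens = "SaCas9")
  agg <- aggregate_replicates(subtract_blank(pm, blank_summary(pm)))
  unt <- agg[agg$condition == "untreated", ]
  inh <- agg[agg$condition == "inhibited", ]
  inh <- inh[match(unt$donor_id, inh$donor_id), ]
  pi <- percent_inhibition(unt$mean_od, inh$mean_od)
  pos <- don$seropositive_sa[match(unt$donor_id, don$donor_id)]
  # seropositive: exactly the 74.7% anchor; seronegative: the 5%
  # nonspecific suppression
  expect_equal(pi[pos], rep(74.7, sum(pos)), tolerance = 1e-9)
  expect_equal(pi[!pos], rep(5, sum(!pos)), tolerance = 1e-9)
})

test_that("noise-free OD response is monotone in true concentration", {
  cfg <- sim_config(noise_cv = 0, blank_sd = 0)
  conc <- sort(runif(50, 0, 2000))
  r <- matrix_retention(cfg$serum_dilution, cfg$matrix_k)
  od <- r * fourpl(conc, cfg$fourpl)
  expect_true(all(diff(od) >= 0))
})

test_that("standard series spans the documented concentration lattice", {
  expect_equal(round(min(standard_concentrations(3000, 4, 7)), 2), 0.73)
  expect_equal(round(min(standard_concentrations(1000, 4, 7)), 2), 0.24)
  expect_error(standard_concentrations(3000, 1, 7), "fold")
  cfg <- sim_config(seed = 2)
  std <- generate_standard_series(cfg, 3000, 4, 7)
  st <- std[std$condition == "standard", ]
  expect_equal(sort(unique(st$spiked_conc)),
               sort(standard_concentrations(3000, 4, 7)))
  expect_error(generate_standard_series(cfg, 3000, 1, 7), "fold")
})

test_that("fixed seed makes the whole generator bit-reproducible", {
  cfg <- sim_config(n_donors = 15, seed = 77)
  a <- generate_measurements(generate_donors(cfg), cfg)
  b <- generate_measurements(generate_donors(cfg), cfg)
  expect_identical(a, b)
})

test_that("null factor effects never inflate the factor tests", {
  # Under the null design the per-factor one-way tests are conservative:
  # every sample appears at every factor level, so sample-to-sample
  # spread inflates the one-way residual and rejection rates fall at or
  # below the nominal 5%.  The practical requirement is that a null
  # panel essentially always yields the fixed-cut-point decision.
  set.seed(42)
  n_rep <- 200
  rej <- matrix(NA, n_rep, 4)
  fixed <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(n_donors = 48, seed = NULL)
    panel <- generate_precision_panel(cfg, n_samples = 24)
    rep_i <- precision_tests(panel)
    rej[i, ] <- rep_i$anova_p[c("analyst", "machine", "run",
                                "plate_position")] < 0.05
    fixed[i] <- rep_i$decision == "fixed"
  }
  expect_true(all(colMeans(rej) <= 0.10))
  expect_gte(mean(fixed), 0.95)
})
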
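# Brute-force oracles and small data builders shared across tests.

# Percentile by explicit sort-and-interpolate at position 1 + p*(n-1);
# independent of stats::quantile().
oracle_percentile <- function(x, p) {
  s <- sort(x)
  pos <- 1 + p * (length(s) - 1)
  lo <- floor(pos)
  hi <- ceiling(pos)
  s[lo] + (pos - lo) * (s[hi] - s[lo])
}

# Cut-point percentile oracle: Weibull plotting position p*(n+1),
# clamped to the observed range.
oracle_tail_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  pos <- min(max(p * (n + 1), 1), n)
  lo <- floor(pos)
  hi <- ceiling(pos)
  s[lo] + (pos - lo) * (s[hi] - s[lo])
}

# Brute-force IQR outlier filter built on the oracle percentile.
oracle_iqr_filter <- function(x, fence = 1.5) {
  q1 <- oracle_percentile(x, 0.25)
  q3 <- oracle_percentile(x, 0.75)
  iqr <- q3 - q1
  x[x >= q1 - fence * iqr & x <= q3 + fence * iqr]
}

# A minimal well-formed plate table with n untreated wells on one plate
# plus quadruplicate blanks.
tiny_plate_table <- function(od = c(1.0, 1.1, 1.2), blank_od = 0.05) {
  wells <- data.frame(donor_id = "D1", antigen = "SaCas9",
                      condition = "untreated", spiked_conc = NA_real_,
                      serum_dilution = 20L,
                      replicate = seq_along(od), analyst = "A1",
                      machine = "M1", run = "plate01",
                      plate_position = "Q1", od450 = od,
                      stringsAsFactors = FALSE)
  blanks <- data.frame(donor_id = "", antigen = "", condition = "blank",
                       spiked_conc = NA_real_, serum_dilution = NA_integer_,
                       replicate = 1:4, analyst = "A1", machine = "M1",
                       run = "plate01", plate_position = "B",
                       od450 = blank_od, stringsAsFactors = FALSE)
  rbind(wells, blanks)
}

# Aggregated training samples (both conditions) for one antigen drawn
# from the generator.
training_samples <- function(config, antigen = "SaCas9") {
  donors <- generate_donors(config)
  pm <- generate_measurements(donors, config, antigens = antigen)
  agg <- aggregate_replicates(subtract_blank(pm, blank_summary(pm)))
  agg[agg$antigen == antigen, ]
}
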
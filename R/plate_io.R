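#' Required columns of a tidy plate table
#'
#' One well per row, comma-delimited, UTF-8.  Empty string means "not
#' applicable" (e.g. `donor_id` for blank wells, `spiked_conc` for serum
#' wells).
#'
#' @return Character vector of required column names, in canonical order.
#' @export
plate_columns <- function() {
  c("donor_id", "antigen", "condition", "spiked_conc", "serum_dilution",
    "replicate", "analyst", "machine", "run", "plate_position", "od450")
}

.conditions <- c("untreated", "inhibited", "blank", "standard")

#' Read and validate a tidy plate table
#'
#' Reads a CSV of single-well OD450 measurements and validates it against
#' the plate-measurement contract: all required columns present, `od450`
#' finite numeric, `replicate >= 1`, `serum_dilution >= 1` where given,
#' `condition` one of `untreated`, `inhibited`, `blank`, `standard`, and
#' blank wells carrying no donor identifier.
#'
#' @param path Path to a CSV file with the columns of [plate_columns()].
#' @return A `data.frame` with one validated well per row.  Row count of
#'   the input file is preserved.
#' @seealso [write_plate_table()], [subtract_blank()],
#'   [aggregate_replicates()]
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) stop("plate table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  missing <- setdiff(plate_columns(), names(raw))
  if (length(missing) > 0) {
    stop("plate table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- raw[, plate_columns()]
  num <- function(col) suppressWarnings(as.numeric(df[[col]]))
  od <- num("od450")
  bad <- which(!is.finite(od))
  if (length(bad) > 0) {
    stop(sprintf("non-numeric or non-finite od450 at row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  df$od450 <- od
  df$spiked_conc <- ifelse(df$spiked_conc == "", NA_real_, num("spiked_conc"))
  df$serum_dilution <- ifelse(df$serum_dilution == "", NA_integer_,
                              as.integer(num("serum_dilution")))
  df$replicate <- as.integer(num("replicate"))
  validate_plate_table(df)
  df
}

#' Write a plate table to CSV
#'
#' Inverse of [read_plate_table()]: numeric fields are written at full
#' precision so a read/write/read cycle round-trips values bit-identically.
#'
#' @param measurements Plate table `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(measurements, path) {
  df <- measurements[, plate_columns()]
  df$od450 <- format(df$od450, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname read_plate_table
#' @param measurements Plate table `data.frame` to validate in place.
#' @export
validate_plate_table <- function(measurements) {
  stopifnot(is.data.frame(measurements))
  missing <- setdiff(plate_columns(), names(measurements))
  if (length(missing) > 0) {
    stop("plate table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(measurements$od450))) {
    stop("od450 must be finite", call. = FALSE)
  }
  if (any(!measurements$condition %in% .conditions)) {
    stop("condition must be one of: ", paste(.conditions, collapse = ", "),
         call. = FALSE)
  }
  if (any(measurements$replicate < 1, na.rm = TRUE)) {
    stop("replicate must be >= 1", call. = FALSE)
  }
  if (any(measurements$serum_dilution < 1, na.rm = TRUE)) {
    stop("serum_dilution must be >= 1 (reciprocal dilution)", call. = FALSE)
  }
  blanks <- measurements$condition == "blank"
  if (any(blanks & !(measurements$donor_id %in% c("", NA)))) {
    stop("blank wells must not carry a donor_id", call. = FALSE)
  }
  invisible(measurements)
}

#' Summarize the blank wells of each plate
#'
#' Blanks (wells with substrate but no serum) are run in quadruplicate on
#' every plate; their mean is subtracted from all serum wells of the same
#' plate, and their standard deviation enters the endpoint-titer threshold
#' (blank mean + 2 SD).  The `run` column identifies the plate.
#'
#' @param measurements Plate table including blank wells.
#' @return `data.frame` with one row per plate: `plate_id`, `mean_blank`,
#'   `sd_blank`, `n_blanks`.
#' @export
blank_summary <- function(measurements) {
  b <- measurements[measurements$condition == "blank", , drop = FALSE]
  if (nrow(b) == 0) {
    stop("no blank wells found on any plate", call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(b$od450, b$run), function(x) {
    data.frame(mean_blank = mean(x),
               sd_blank = if (length(x) > 1) stats::sd(x) else 0,
               n_blanks = length(x))
  }))
  data.frame(plate_id = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Subtract per-plate blank means from serum wells
#'
#' Each well's OD450 is decremented by the mean blank of its own plate;
#' blank sharing across plates is not allowed.  Corrected values at or
#' below zero are floored at `floor` OD so that downstream
#' log-transformation is defined.  Blank wells are dropped from the
#' output.
#'
#' @param measurements Plate table (blank wells may be present or absent).
#' @param blanks Output of [blank_summary()] covering every plate in
#'   `measurements`.
#' @param floor Lower bound applied to corrected ODs (default 0.001).
#' @return Plate table of non-blank wells with blank-corrected `od450`.
#' @export
subtract_blank <- function(measurements, blanks, floor = 0.001) {
  m <- measurements[measurements$condition != "blank", , drop = FALSE]
  if (nrow(m) == 0) return(m)
  idx <- match(m$run, blanks$plate_id)
  if (anyNA(idx)) {
    stop("no blank summary for plate(s): ",
         paste(unique(m$run[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  m$od450 <- pmax(m$od450 - blanks$mean_blank[idx], floor)
  m
}

#' Aggregate well replicates into per-sample results
#'
#' Collapses blank-corrected wells to one row per
#' (donor, antigen, condition, dilution, spiked concentration) group:
#' the replicate mean, the sample standard deviation (n - 1 denominator;
#' 0 for a single replicate) and the replicate count.  The result is
#' independent of input row order.
#'
#' @param measurements Blank-corrected plate table.
#' @return `data.frame` of sample results: `donor_id`, `antigen`,
#'   `condition`, `serum_dilution`, `spiked_conc`, `mean_od`, `sd_od`,
#'   `n_replicates`.
#' @export
aggregate_replicates <- function(measurements) {
  m <- measurements
  if (nrow(m) == 0) {
    warning("no measurements to aggregate")
    return(data.frame(donor_id = character(), antigen = character(),
                      condition = character(), serum_dilution = integer(),
                      spiked_conc = numeric(), mean_od = numeric(),
                      sd_od = numeric(), n_replicates = integer()))
  }
  key <- interaction(m$donor_id, m$antigen, m$condition,
                     ifelse(is.na(m$serum_dilution), -1L, m$serum_dilution),
                     ifelse(is.na(m$spiked_conc), -1, m$spiked_conc),
                     drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(m)), key)
  out <- do.call(rbind, lapply(groups, function(i) {
    x <- m$od450[i]
    data.frame(donor_id = m$donor_id[i[1]],
               antigen = m$antigen[i[1]],
               condition = m$condition[i[1]],
               serum_dilution = m$serum_dilution[i[1]],
               spiked_conc = m$spiked_conc[i[1]],
               mean_od = mean(x),
               sd_od = if (length(x) > 1) stats::sd(x) else 0,
               n_replicates = length(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
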
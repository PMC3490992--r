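## Specimen-level measurements and the derived predictors used by the
## candidate models.
##
## Each specimen carries tooth counts, upper/lower tooth-row OPCR, and four
## occlusion measures: lateral translation t (mm), ventral rotational
## distance d (mm), sagittal occlusal angle a (degrees from vertical), and
## glenoid fossae width w (mm; a body-size proxy). Relative motion measures
## divide t and d by w before the natural log transform.

SPECIMEN_COLUMNS <- c("order_name", "family", "genus", "species", "collection",
                      "number", "n_upper_teeth", "n_lower_teeth",
                      "upper_opcr", "lower_opcr", "t", "d", "a", "w")

#' Load a specimen measurement table
#'
#' Reads a CSV with one row per museum specimen, or the table packaged with
#' opcrkin: 34 carnivoran (20) and dasyuromorph (14) specimens with tooth
#' counts, upper/lower tooth-row OPCR and the four mandibular-motion measures.
#'
#' @param path path to a CSV with the columns
#'   `r paste(SPECIMEN_COLUMNS, collapse = ", ")`, or `"table1"` (default)
#'   for the packaged 34-specimen table.
#' @return A `data.frame` of class `specimen_table`.
#' @export
load_specimen_table <- function(path = "table1") {
  if (identical(path, "table1"))
    path <- system.file("extdata", "table1_specimens.csv", package = "opcrkin",
                        mustWork = TRUE)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop(sprintf("specimen table schema error: %s",
                                conditionMessage(e)), call. = FALSE))
  missing_cols <- setdiff(SPECIMEN_COLUMNS, names(df))
  if (length(missing_cols))
    stop(sprintf("specimen table schema error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  num_cols <- c("n_upper_teeth", "n_lower_teeth", "upper_opcr", "lower_opcr",
                "t", "d", "a", "w")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop(sprintf("specimen table parse error: non-numeric '%s' in row %d",
                   col, bad[1]), call. = FALSE)
    df[[col]] <- v
  }
  validate_specimens(df)
  class(df) <- c("specimen_table", "data.frame")
  df
}

validate_specimens <- function(df) {
  check_pos <- function(col, upper = Inf) {
    bad <- which(df[[col]] <= 0 | df[[col]] >= upper)
    if (length(bad))
      stop(sprintf("specimen domain error: '%s' out of range in row %d",
                   col, bad[1]), call. = FALSE)
  }
  for (col in c("t", "d", "w", "upper_opcr", "lower_opcr")) check_pos(col)
  check_pos("a", upper = 90)
  for (col in c("n_upper_teeth", "n_lower_teeth")) {
    bad <- which(df[[col]] < 1 | df[[col]] != round(df[[col]]))
    if (length(bad))
      stop(sprintf("specimen domain error: '%s' must be a positive integer (row %d)",
                   col, bad[1]), call. = FALSE)
  }
  invisible(df)
}

#' Derive the log-transformed measures used by the models
#'
#' Adds, per specimen: `ln_upper` and `ln_lower` (natural logs of tooth-row
#' OPCR), `rt = ln(t / w)` (relative lateral translation), `rd = ln(d / w)`
#' (relative ventral rotational distance), `ln_a` (log sagittal occlusal
#' angle), and `avg_upper` / `avg_lower` (tooth-row OPCR divided by tooth
#' count; not yet log transformed).
#'
#' @param specimens a `specimen_table` (or data.frame with its columns).
#' @return The input with the seven derived columns appended.
#' @examples
#' tab <- derive_measures(load_specimen_table())
#' tab$rt[1]   # ln(3.22 / 56.20)
#' @export
derive_measures <- function(specimens) {
  df <- as.data.frame(specimens)
  for (col in c("t", "d", "a", "w", "upper_opcr", "lower_opcr")) {
    if (is.null(df[[col]]))
      stop(sprintf("specimen domain error: column '%s' missing", col), call. = FALSE)
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad))
      stop(sprintf("specimen domain error: nonpositive '%s' in row %d",
                   col, bad[1]), call. = FALSE)
  }
  df$ln_upper <- log(df$upper_opcr)
  df$ln_lower <- log(df$lower_opcr)
  df$rt <- log(df$t / df$w)
  df$rd <- log(df$d / df$w)
  df$ln_a <- log(df$a)
  df$avg_upper <- average_tooth_opcr(df$upper_opcr, df$n_upper_teeth)
  df$avg_lower <- average_tooth_opcr(df$lower_opcr, df$n_lower_teeth)
  class(df) <- c("specimen_table", "data.frame")
  df
}
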
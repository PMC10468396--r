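# Numeric columns are written with 17 significant digits so that doubles
# survive a write/read cycle bit-identically.
fmt_full <- function(x) {
  if (!is.numeric(x)) return(as.character(x))
  out <- formatC(x, digits = 17, format = "g", flag = "-")
  trimws(out)
}

write_plain_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_full), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write colony time-course CSV files
#'
#' The colony schema is
#' `colony_id,day,visible_area_cm2,mass_g,mgv,true_count,obs_density_cells_cm2`.
#' Numeric values are written with full precision, so a write/read round trip
#' reproduces the values exactly.
#'
#' @param timecourse A colony time-course tibble
#'   (see [generate_colony_timecourse()]).
#' @param path File path.
#' @return `write_colony_csv` returns `path` invisibly; `read_colony_csv`
#'   returns a tibble in the colony schema.
#' @export
write_colony_csv <- function(timecourse, path) {
  cols <- c("colony_id", "day", "visible_area_cm2", "mass_g", "mgv",
            "true_count", "obs_density_cells_cm2")
  stopifnot(all(cols %in% names(timecourse)))
  write_plain_csv(timecourse[cols], path)
}

#' @rdname write_colony_csv
#' @export
read_colony_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(colony_id = "character",
                                       day = "integer",
                                       visible_area_cm2 = "numeric",
                                       mass_g = "numeric",
                                       mgv = "numeric",
                                       true_count = "numeric",
                                       obs_density_cells_cm2 = "numeric"))
  tibble::as_tibble(df)
}

#' Read and write drawdown CSV files
#'
#' Schema `minute,conc_uM`. The tank volume and series label are not part of
#' the CSV and must be supplied when reading.
#'
#' @param series A [drawdown_series].
#' @param path File path.
#' @param volume Tank volume in L (for reading).
#' @param label Series label (for reading).
#' @return `write_drawdown_csv` returns `path` invisibly; `read_drawdown_csv`
#'   returns a [drawdown_series].
#' @export
write_drawdown_csv <- function(series, path) {
  stopifnot(inherits(series, "drawdown_series"))
  write_plain_csv(
    data.frame(minute = series$minutes, conc_uM = series$conc), path)
}

#' @rdname write_drawdown_csv
#' @export
read_drawdown_csv <- function(path, volume, label = "treatment") {
  df <- utils::read.csv(path, colClasses = c("numeric", "numeric"))
  drawdown_series(df$minute, df$conc_uM, volume = volume, label = label)
}

#' Read and write field isotope CSV files
#'
#' Schema `group,compartment,delta15N_permil`.
#'
#' @param samples A tibble of isotope samples
#'   (see [generate_field_isotopes()]).
#' @param path File path.
#' @return `write_isotope_csv` returns `path` invisibly; `read_isotope_csv`
#'   returns a tibble.
#' @export
write_isotope_csv <- function(samples, path) {
  cols <- c("group", "compartment", "delta15N_permil")
  stopifnot(all(cols %in% names(samples)))
  write_plain_csv(samples[cols], path)
}

#' @rdname write_isotope_csv
#' @export
read_isotope_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
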
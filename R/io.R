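#' Read a concentration time series from tidy CSV
#'
#' Expects columns `time_h`, `species`, `fraction` (long format, one row
#' per time point and species).  Rows are validated: fractions must lie
#' in \[0, 1\] and each `(time, species)` pair may appear only once;
#' offending rows are reported with their line numbers (header = line 1).
#'
#' @param path Path to a CSV file.
#' @return A `migkin_series`.
#' @export
read_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_h", "species", "fraction")
  if (!all(needed %in% names(df))) {
    stop("series file must have columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(df) == 0) stop("no observations in '", path, "'")
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- !is.finite(df$time_h) | !is.finite(df$fraction)
  if (any(bad)) {
    stop("malformed rows (non-numeric time or fraction) at line(s): ",
         paste(line[bad], collapse = ", "))
  }
  out_of_range <- df$fraction < 0 | df$fraction > 1
  if (any(out_of_range)) {
    stop("fraction outside [0, 1] at line(s): ",
         paste(line[out_of_range], collapse = ", "))
  }
  dup <- duplicated(df[, c("time_h", "species")])
  if (any(dup)) {
    stop("duplicate (time, species) rows at line(s): ",
         paste(line[dup], collapse = ", "))
  }
  times <- sort(unique(df$time_h))
  species <- unique(df$species)
  vals <- matrix(NA_real_, length(times), length(species),
                 dimnames = list(NULL, species))
  vals[cbind(match(df$time_h, times), match(df$species, species))] <-
    df$fraction
  if (anyNA(vals)) {
    stop("series is not complete: every species needs a value at every time")
  }
  concentration_series(times, vals, species)
}

#' Write a concentration time series as tidy CSV
#'
#' @param series A `migkin_series`.
#' @param path Output path; columns `time_h`, `species`, `fraction`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a pH trajectory from CSV
#'
#' Expects columns `time_h` and `ph`.
#'
#' @param path Path to a CSV file.
#' @param reference_ph Reference pH of the rate constants.
#' @return A `migkin_ph`.
#' @export
read_ph_trajectory <- function(path, reference_ph = 8) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "ph") %in% names(df))) {
    stop("pH file must have columns: time_h, ph")
  }
  if (nrow(df) == 0) stop("no pH observations in '", path, "'")
  df <- df[order(df$time_h), ]
  ph_trajectory(df$time_h, df$ph, reference_ph = reference_ph)
}

#' Write a pH trajectory as CSV
#'
#' @param ph A `migkin_ph`.
#' @param path Output path; columns `time_h`, `ph`.
#' @return `path`, invisibly.
#' @export
write_ph_trajectory <- function(ph, path) {
  write.csv(data.frame(time_h = ph$times, ph = ph$ph), path,
            row.names = FALSE)
  invisible(path)
}

#' Read a table of aqueous free energies
#'
#' Expects columns `label`, `g_neutral`, `g_anion` and `unit` (`"kcal"`
#' or `"hartree"`; hartree values are converted).  Returns the input
#' augmented with the pKa of each hydroxyl via
#' [pka_from_free_energies()].
#'
#' @param path Path to a CSV file.
#' @param constants A [thermo_constants()] list.
#' @return Data frame with columns `label`, `g_neutral`, `g_anion`
#'   (kcal/mol) and `pka`.
#' @export
read_free_energies <- function(path, constants = thermo_constants()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("label", "g_neutral", "g_anion", "unit")
  if (!all(needed %in% names(df))) {
    stop("free-energy file must have columns: ",
         paste(needed, collapse = ", "))
  }
  bad_unit <- !df$unit %in% c("kcal", "hartree")
  if (any(bad_unit)) {
    stop("unknown unit(s): ", paste(unique(df$unit[bad_unit]),
                                    collapse = ", "))
  }
  hart <- df$unit == "hartree"
  df$g_neutral[hart] <- df$g_neutral[hart] * constants$hartree_to_kcal
  df$g_anion[hart] <- df$g_anion[hart] * constants$hartree_to_kcal
  df$unit <- NULL
  df$pka <- pka_from_free_energies(df$g_neutral, df$g_anion, constants)
  df
}
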
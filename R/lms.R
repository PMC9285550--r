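# LMS (Box-Cox) growth-reference transforms and reference tables.
#
# A growth reference tabulates, by sex and age, the three LMS parameters:
# L (Box-Cox power, governs skewness), M (median, kg/m^2 for BMI) and
# S (coefficient of variation). A measurement x maps to a z-score via
#   z = ((x/M)^L - 1) / (L*S)      for L != 0
#   z = log(x/M) / S               for L == 0
# and back. All three BMI references handled here (IOTF, WHO, CDC) use
# this representation.

# switch point below which the power branch is replaced by the log branch
# to avoid catastrophic cancellation in ((x/M)^L - 1)/L
.lms_L_tol <- 1e-7

#' Convert a measurement to an LMS z-score
#'
#' Applies the Box-Cox (LMS) transform `z = ((x/M)^L - 1)/(L*S)`, with the
#' logarithmic limit `z = log(x/M)/S` used when `|L|` is numerically zero.
#'
#' @param x Measurement (e.g. BMI in kg/m^2); must be positive.
#' @param L Box-Cox power (unitless).
#' @param M Median of the reference distribution; must be positive.
#' @param S Coefficient of variation; must be positive.
#' @return z-score(s), strictly increasing in `x`.
#' @examples
#' z_from_bmi(22, L = 1, M = 20, S = 0.1)   # (22/20 - 1)/0.1 = 1
#' z_from_bmi(20, L = -1.5, M = 20, S = 0.1) # median maps to 0
#' @seealso [bmi_from_z()] for the inverse transform.
#' @export
z_from_bmi <- function(x, L, M, S) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("measurement 'x' must be positive and finite")
  .check_lms(L, M, S)
  k <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, k); L <- rep_len(L, k)
  M <- rep_len(M, k); S <- rep_len(S, k)
  r <- x / M
  ifelse(abs(L) > .lms_L_tol, (r^L - 1) / (L * S), log(r) / S)
}

#' Convert an LMS z-score to a measurement
#'
#' Inverts [z_from_bmi()]: `x = M*(1 + L*S*z)^(1/L)` (or `M*exp(S*z)` in the
#' `L = 0` limit). For `L != 0` the z-score must satisfy the support
#' condition `1 + L*S*z > 0`; outside it the Box-Cox distribution assigns
#' no measurement to that z-score.
#'
#' @inheritParams z_from_bmi
#' @param z z-score(s).
#' @return Measurement(s) on the original scale.
#' @examples
#' bmi_from_z(0, L = -1.6, M = 16, S = 0.11)  # the median
#' bmi_from_z(z_from_bmi(25, 1.2, 18, 0.1), 1.2, 18, 0.1)  # round trip
#' @export
bmi_from_z <- function(z, L, M, S) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("'z' must be finite")
  .check_lms(L, M, S)
  k <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, k); L <- rep_len(L, k)
  M <- rep_len(M, k); S <- rep_len(S, k)
  base <- 1 + L * S * z
  power <- abs(L) > .lms_L_tol
  if (any(power & base <= 0)) {
    bad <- z[power & base <= 0]
    stop(sprintf("z-score %g lies outside the support of the Box-Cox distribution (1 + L*S*z <= 0)",
                 bad[1]))
  }
  ifelse(power, M * base^(1 / L), M * exp(S * z))
}

.check_lms <- function(L, M, S) {
  if (!is.numeric(L) || any(!is.finite(L)))
    stop("'L' must be finite")
  if (!is.numeric(M) || any(!is.finite(M)) || any(M <= 0))
    stop("'M' must be positive and finite")
  if (!is.numeric(S) || any(!is.finite(S)) || any(S <= 0))
    stop("'S' must be positive and finite")
  invisible(TRUE)
}

#' Construct a growth-reference table
#'
#' A `reference_table` holds the LMS parameters of one growth reference on
#' a discrete age grid, separately by sex. Ages must be strictly increasing
#' within each sex, and `M` and `S` positive throughout.
#'
#' @param name Short identifier for the reference (e.g. `"WHO"`).
#' @param data Data frame with columns `sex` (`"male"`/`"female"`), `age`
#'   (decimal years), `L`, `M`, `S`. Rows with `sex == "both"` are
#'   duplicated into each sex.
#' @return An object of class `reference_table`.
#' @seealso [lms_at()], [read_reference_csv()], [make_reference()]
#' @export
reference_table <- function(name, data) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  required <- c("sex", "age", "L", "M", "S")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("reference table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)[required]
  data$sex <- tolower(as.character(data$sex))
  if ("both" %in% data$sex) {
    shared <- data[data$sex == "both", ]
    data <- rbind(data[data$sex != "both", ],
                  transform(shared, sex = "male"),
                  transform(shared, sex = "female"))
  }
  bad_sex <- setdiff(unique(data$sex), c("male", "female"))
  if (length(bad_sex))
    stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "))
  for (col in c("age", "L", "M", "S"))
    if (!is.numeric(data[[col]]) || any(!is.finite(data[[col]])))
      stop(sprintf("column '%s' must be numeric and finite", col))
  data <- data[order(match(data$sex, c("male", "female")), data$age), ]
  rownames(data) <- NULL
  for (sx in unique(data$sex)) {
    ages <- data$age[data$sex == sx]
    dup <- which(diff(ages) <= 0)
    if (length(dup))
      stop(sprintf("ages must be strictly increasing within sex '%s' (violated at age %g)",
                   sx, ages[dup[1] + 1L]))
  }
  if (any(data$M <= 0)) stop("'M' must be positive throughout")
  if (any(data$S <= 0)) stop("'S' must be positive throughout")
  structure(list(name = name, data = data,
                 single_sex = length(unique(data$sex)) < 2L),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  sxs <- unique(x$data$sex)
  cat(sprintf("<reference_table> %s: %d rows", x$name, nrow(x$data)))
  for (sx in sxs) {
    sp <- age_span(x, sx)
    cat(sprintf("\n  %s: ages %g-%g y (%d grid points)",
                sx, sp[1], sp[2], sum(x$data$sex == sx)))
  }
  cat("\n")
  invisible(x)
}

#' Covered age span of a reference table
#'
#' @param table A [reference_table()].
#' @param sex `"male"` or `"female"`.
#' @return Numeric vector `c(min, max)` in years.
#' @export
age_span <- function(table, sex) {
  sex <- normalize_sex(sex)
  ages <- table$data$age[table$data$sex == sex]
  if (!length(ages))
    stop(sprintf("reference '%s' has no rows for sex '%s'", table$name, sex))
  range(ages)
}

# Accepts the synonyms in common use in surveillance datasets.
normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- c(male = "male", m = "male", boys = "male", boy = "male",
           female = "female", f = "female", girls = "female", girl = "female",
           both = "both", b = "both")[s]
  if (any(is.na(out)))
    stop("unknown sex: ", paste(s[is.na(out)], collapse = ", "))
  unname(out)
}

#' Interpolate LMS parameters at an age
#'
#' Linear interpolation of L, M and S separately between the bracketing
#' grid rows; grid ages return the tabulated values unchanged. No
#' extrapolation is performed.
#'
#' @param table A [reference_table()].
#' @param sex `"male"` or `"female"`.
#' @param age Age(s) in years, inside the covered span.
#' @return A list with numeric components `L`, `M`, `S` of `length(age)`.
#' @export
lms_at <- function(table, sex, age) {
  sex <- normalize_sex(sex)
  if (identical(sex, "both"))
    stop("sex must be 'male' or 'female' for LMS interpolation")
  rows <- table$data[table$data$sex == sex, ]
  if (!nrow(rows))
    stop(sprintf("reference '%s' has no rows for sex '%s'", table$name, sex))
  sp <- range(rows$age)
  if (any(age < sp[1] - 1e-9 | age > sp[2] + 1e-9))
    stop(sprintf("age %g outside the span %g-%g y covered by reference '%s' (%s)",
                 age[which(age < sp[1] - 1e-9 | age > sp[2] + 1e-9)][1],
                 sp[1], sp[2], table$name, sex))
  age <- pmin(pmax(age, sp[1]), sp[2])
  list(L = stats::approx(rows$age, rows$L, xout = age)$y,
       M = stats::approx(rows$age, rows$M, xout = age)$y,
       S = stats::approx(rows$age, rows$S, xout = age)$y)
}

#' Read a growth-reference table from CSV
#'
#' Expects a comma-separated file with header `sex,age,L,M,S`; `sex` may be
#' `male`, `female` or `both` (duplicated into each sex on load), `age` is
#' in decimal years with `.` as decimal separator.
#'
#' @param path Path to the CSV file.
#' @param name Reference name; defaults to the file name without extension.
#' @return A [reference_table()].
#' @export
read_reference_csv <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sex", "age", "L", "M", "S")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop(sprintf("'%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  for (col in c("age", "L", "M", "S")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (any(is.na(v)))
      stop(sprintf("'%s': non-numeric value in column '%s' at data row %d",
                   path, col, if (length(bad)) bad[1] else which(is.na(v))[1]))
    raw[[col]] <- v
  }
  # report unsorted ages with the offending row before the constructor runs
  raw$sex <- tolower(as.character(raw$sex))
  for (sx in setdiff(unique(raw$sex), NA)) {
    ages <- raw$age[raw$sex == sx]
    idx <- which(raw$sex == sx)
    dup <- which(diff(ages) <= 0)
    if (length(dup))
      stop(sprintf("'%s': ages not strictly increasing for sex '%s' at data row %d",
                   path, sx, idx[dup[1] + 1L]))
  }
  reference_table(name, raw)
}

#' Write a growth-reference table to CSV
#'
#' Writes the canonical `sex,age,L,M,S` schema; `write` then `read` is the
#' identity on such files.
#'
#' @param table A [reference_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(table, path) {
  stopifnot(inherits(table, "reference_table"))
  utils::write.csv(table$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
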
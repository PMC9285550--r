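# Cut-off distances on a common z-score scale.
#
# Two cut-offs defined on different references are compared by
# back-transforming each to BMI at the given age and sex and re-scoring
# that BMI on the other reference. Each cut-off then has two z-scores --
# its own and the cross one -- whose mean is a symmetric estimate of its
# position; the difference of the two means is the cut-off distance dz.

#' Score a cut-off's BMI value on another reference
#'
#' Back-transforms the cut-off z-score to BMI on its own reference at the
#' given age and sex, then transforms that BMI to a z-score on
#' `scoring_ref`. With `scoring_ref` equal to the cut-off's own reference
#' the result is the cut-off z itself.
#'
#' @param cutoff A resolved [cutoff_spec()] (scalar `z`).
#' @param scoring_ref A [reference_table()] to score the BMI on.
#' @param sex `"male"` or `"female"`.
#' @param age Age in years (inside both references' spans).
#' @param refs Named list of [reference_table()]s containing the cut-off's
#'   own reference under `cutoff$reference`.
#' @return The cross z-score (a single number).
#' @export
cross_z <- function(cutoff, scoring_ref, sex, age, refs) {
  stopifnot(inherits(cutoff, "cutoff_spec"), length(cutoff$z) == 1L,
            inherits(scoring_ref, "reference_table"))
  own <- refs[[cutoff$reference]]
  if (is.null(own))
    stop(sprintf("reference table '%s' (own reference of '%s') not supplied",
                 cutoff$reference, cutoff$label))
  sex <- normalize_sex(sex)
  own_lms <- tryCatch(lms_at(own, sex, age), error = function(e)
    stop(sprintf("reference '%s': %s", own$name, conditionMessage(e))))
  bmi <- bmi_from_z(cutoff$z, own_lms$L, own_lms$M, own_lms$S)
  sc_lms <- tryCatch(lms_at(scoring_ref, sex, age), error = function(e)
    stop(sprintf("reference '%s': %s", scoring_ref$name, conditionMessage(e))))
  z_from_bmi(bmi, sc_lms$L, sc_lms$M, sc_lms$S)
}

# shared assembly used by cutoff_distance() and the worked-example fixture
.new_cutoff_distance <- function(label_A, label_B, sex, age,
                                 z_A, z_B, z_A_onB, z_B_onA,
                                 category = NA_character_) {
  zbar_A <- (z_A + z_A_onB) / 2
  zbar_B <- (z_B + z_B_onA) / 2
  structure(list(pair = c(A = label_A, B = label_B), sex = sex, age = age,
                 category = category,
                 z_A = z_A, z_B = z_B, z_A_onB = z_A_onB, z_B_onA = z_B_onA,
                 zbar_A = zbar_A, zbar_B = zbar_B, dz = zbar_B - zbar_A),
            class = "cutoff_distance")
}

#' z-score distance between two cut-offs
#'
#' Computes the four z-scores placing cut-offs A and B on both references
#' at the given age and sex, their symmetric means `zbar_A` and `zbar_B`,
#' and the distance
#' `dz = zbar_B - zbar_A = ((z_B - z_A) + (z_B_onA - z_A_onB)) / 2`.
#' Swapping A and B negates `dz` exactly.
#'
#' @param label_A,label_B Cut-off labels resolvable in `registry`.
#' @param sex `"male"` or `"female"`.
#' @param age Age in years.
#' @param refs Named list of [reference_table()]s.
#' @param registry A [cutoff_registry()].
#' @return An object of class `cutoff_distance`.
#' @export
cutoff_distance <- function(label_A, label_B, sex, age, refs,
                            registry = default_cutoffs()) {
  sex <- normalize_sex(sex)
  A <- resolve_cutoff(registry, label_A, sex, age)
  B <- resolve_cutoff(registry, label_B, sex, age)
  ref_A <- refs[[A$reference]]
  ref_B <- refs[[B$reference]]
  if (is.null(ref_A) || is.null(ref_B))
    stop("both cut-offs' reference tables must be supplied in 'refs'")
  .new_cutoff_distance(
    A$label, B$label, sex, age,
    z_A = A$z, z_B = B$z,
    z_A_onB = cross_z(A, ref_B, sex, age, refs),
    z_B_onA = cross_z(B, ref_A, sex, age, refs),
    category = if (identical(A$category, B$category)) A$category else NA_character_)
}

#' @export
print.cutoff_distance <- function(x, ...) {
  cat(sprintf("<cutoff_distance> %s vs %s, %s, age %g y\n",
              x$pair["A"], x$pair["B"], x$sex, x$age))
  cat(sprintf("  z_A = %.2f (on B: %.2f)  zbar_A = %.2f\n",
              x$z_A, x$z_A_onB, round_half_up(x$zbar_A, 2)))
  cat(sprintf("  z_B = %.2f (on A: %.2f)  zbar_B = %.2f\n",
              x$z_B, x$z_B_onA, round_half_up(x$zbar_B, 2)))
  cat(sprintf("  dz = %.2f\n",
              round_half_up(x$zbar_B, 2) - round_half_up(x$zbar_A, 2)))
  invisible(x)
}

# "A:B" -> c("A", "B"); lists/two-column input pass through
.parse_pairs <- function(pairs) {
  if (is.character(pairs)) pairs <- strsplit(pairs, ":", fixed = TRUE)
  pairs <- lapply(pairs, function(p) {
    p <- trimws(as.character(p))
    if (length(p) != 2L) stop("each pair must name exactly two cut-offs")
    p
  })
  if (!length(pairs)) stop("at least one cut-off pair is required")
  pairs
}

#' Build a dz look-up table over an age-sex grid
#'
#' One row per (pair, sex, age) combination, computed by
#' [cutoff_distance()]. Grid ages at which a cut-off is not defined are
#' omitted rather than raising an error.
#'
#' @param refs Named list of [reference_table()]s.
#' @param registry A [cutoff_registry()].
#' @param pairs Cut-off pairs: character `"A:B"` entries or a list of
#'   length-2 character vectors.
#' @param sexes Sexes to tabulate.
#' @param ages Age grid in years; default half-years from 2 to 18.
#' @return Data frame with columns `pair_A, pair_B, sex, age, z_A, z_B,
#'   z_B_onA, z_A_onB, dz` (full precision).
#' @seealso [lookup_dz()], [write_dz_csv()]
#' @export
build_lookup_table <- function(refs, registry = default_cutoffs(), pairs,
                               sexes = c("male", "female"),
                               ages = seq(2, 18, by = 0.5)) {
  pairs <- .parse_pairs(pairs)
  sexes <- vapply(sexes, normalize_sex, "")
  rows <- list()
  for (p in pairs) for (sx in sexes) for (a in ages) {
    d <- tryCatch(cutoff_distance(p[1], p[2], sx, a, refs, registry),
                  error = function(e) NULL, warning = function(w) NULL)
    if (is.null(d)) next
    rows[[length(rows) + 1L]] <- data.frame(
      pair_A = d$pair[["A"]], pair_B = d$pair[["B"]], sex = sx, age = a,
      z_A = d$z_A, z_B = d$z_B, z_B_onA = d$z_B_onA, z_A_onB = d$z_A_onB,
      dz = d$dz, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no (pair, sex, age) combination could be resolved")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Look up dz at the grid age nearest a group's mean age
#'
#' Exact-midpoint ties round to the younger age. If the table holds the
#' pair only in reversed orientation, the negated `dz` is returned.
#'
#' @param table A look-up table from [build_lookup_table()] or
#'   [read_dz_csv()].
#' @param pair Length-2 character vector `c(A, B)` or `"A:B"`.
#' @param sex `"male"` or `"female"`.
#' @param group_mean_age Mean age of the target group, years.
#' @return `dz` (a single number).
#' @export
lookup_dz <- function(table, pair, sex, group_mean_age) {
  pair <- if (is.character(pair) && length(pair) == 1L)
    .parse_pairs(pair)[[1]] else .parse_pairs(list(pair))[[1]]
  sex <- normalize_sex(sex)
  rows <- table[table$pair_A == pair[1] & table$pair_B == pair[2] &
                  table$sex == sex, ]
  flip <- 1
  if (!nrow(rows)) {
    rows <- table[table$pair_A == pair[2] & table$pair_B == pair[1] &
                    table$sex == sex, ]
    flip <- -1
  }
  if (!nrow(rows))
    stop(sprintf("pair %s:%s (%s) not present in the look-up table",
                 pair[1], pair[2], sex))
  gap <- abs(rows$age - group_mean_age)
  hit <- which(gap < min(gap) + 1e-9)
  row <- rows[hit[which.min(rows$age[hit])], ]  # tie -> younger age
  flip * row$dz
}

#' Write / read a dz look-up table as CSV
#'
#' The file stores `dz` (and the four z-scores) rounded to 3 decimal
#' places; keep the in-memory table when full precision matters.
#'
#' @param table Look-up table from [build_lookup_table()].
#' @param path File path.
#' @return `path` invisibly (write); the table (read).
#' @export
write_dz_csv <- function(table, path) {
  out <- table
  for (col in c("z_A", "z_B", "z_B_onA", "z_A_onB", "dz"))
    out[[col]] <- round(out[[col]], 3)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dz_csv
#' @export
read_dz_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("pair_A", "pair_B", "sex", "age", "dz")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop(sprintf("'%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  tab
}
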
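# Named z-score cut-offs and the registry of standard definitions.
#
# Each cut-off is a fixed z-score on one reference, tied to a category
# (thinness / overweight / obesity) and an age range. The standard
# definitions: IOTF uses sex-specific z values chosen so the centile
# passes through BMI 16/17/18.5/25/30 at age 18; WHO uses -2/+1/+2 from
# age 5 (and -2/+2/+3 below 5); CDC uses the 5th/85th/95th centiles.

#' Define a z-score cut-off
#'
#' @param label Display name, e.g. `"IOTF 25"` or `"WHO +1"`.
#' @param reference Name of the reference the z-score is defined on.
#' @param category One of `"thinness"`, `"overweight"`, `"obesity"`.
#' @param z Cut-off z-score: a single number shared by both sexes, or a
#'   named vector `c(male = , female = )`. Must be negative for thinness
#'   and positive for overweight/obesity.
#' @param age_min,age_max Age range (years) the definition applies to.
#'   When two entries share a boundary age (e.g. the WHO switch at 5 y),
#'   the boundary age resolves to the older band.
#' @return An object of class `cutoff_spec`.
#' @export
cutoff_spec <- function(label, reference, category, z,
                        age_min = 2, age_max = 18) {
  category <- match.arg(category, c("thinness", "overweight", "obesity"))
  stopifnot(is.numeric(z), length(z) %in% 1:2, age_min < age_max)
  if (length(z) == 2L && !setequal(names(z), c("male", "female")))
    stop("sex-specific 'z' must be named c(male = , female = )")
  if (any(z == 0)) stop("cut-off z must be non-zero")
  sign_required <- if (category == "thinness") -1 else 1
  if (any(sign(z) != sign_required))
    stop(sprintf("'%s' cut-offs must have %s z-scores", category,
                 if (sign_required > 0) "positive" else "negative"))
  structure(list(label = label, reference = reference, category = category,
                 z = z, sign = sign_required,
                 age_min = age_min, age_max = age_max),
            class = "cutoff_spec")
}

#' @export
print.cutoff_spec <- function(x, ...) {
  zs <- if (length(x$z) == 1L) format(x$z) else
    sprintf("male %s / female %s", format(x$z[["male"]]), format(x$z[["female"]]))
  cat(sprintf("<cutoff_spec> %s: %s %s, z = %s, ages %g-%g y\n",
              x$label, x$reference, x$category, zs, x$age_min, x$age_max))
  invisible(x)
}

#' Build a cut-off registry
#'
#' A registry is an ordered collection of [cutoff_spec()] entries,
#' queryable by label (or by `"<reference> <category>"` alias), sex and
#' age via [resolve_cutoff()].
#'
#' @param ... `cutoff_spec` objects, or a single list of them.
#' @return An object of class `cutoff_registry`.
#' @export
cutoff_registry <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1]], "cutoff_spec"))
    specs <- specs[[1]]
  if (!length(specs) || !all(vapply(specs, inherits, TRUE, "cutoff_spec")))
    stop("a registry needs at least one 'cutoff_spec'")
  structure(specs, class = "cutoff_registry")
}

#' @export
print.cutoff_registry <- function(x, ...) {
  cat(sprintf("<cutoff_registry> %d cut-off definitions\n", length(x)))
  for (s in x) print(s)
  invisible(x)
}

#' The standard cut-off registry
#'
#' Preloaded with the IOTF, WHO and CDC definitions of thinness,
#' overweight and obesity: IOTF thinness grades 1-3 (BMI 18.5/17/16 at
#' age 18; boys z -1.01/-1.88/-2.56, girls -0.98/-1.79/-2.44), IOTF
#' overweight (boys +1.31, girls +1.24) and obesity (boys +2.29, girls
#' +2.19) over ages 2-18; WHO -2/+1/+2 from age 5 and -2/+2/+3 below
#' age 5 (BMI-for-age throughout -- below age 5 this approximates the
#' weight-for-height definition); CDC -1.64/+1.04/+1.64 (5th/85th/95th
#' centiles) over ages 2-20.
#'
#' @return A [cutoff_registry()].
#' @export
default_cutoffs <- function() {
  cutoff_registry(
    cutoff_spec("IOTF 18.5", "IOTF", "thinness",
                c(male = -1.01, female = -0.98), 2, 18),
    cutoff_spec("IOTF 17", "IOTF", "thinness",
                c(male = -1.88, female = -1.79), 2, 18),
    cutoff_spec("IOTF 16", "IOTF", "thinness",
                c(male = -2.56, female = -2.44), 2, 18),
    cutoff_spec("IOTF 25", "IOTF", "overweight",
                c(male = 1.31, female = 1.24), 2, 18),
    cutoff_spec("IOTF 30", "IOTF", "obesity",
                c(male = 2.29, female = 2.19), 2, 18),
    cutoff_spec("WHO -2", "WHO", "thinness", -2, 2, 19),
    cutoff_spec("WHO +2", "WHO", "overweight", 2, 2, 5),
    cutoff_spec("WHO +3", "WHO", "obesity", 3, 2, 5),
    cutoff_spec("WHO +1", "WHO", "overweight", 1, 5, 19),
    cutoff_spec("WHO +2", "WHO", "obesity", 2, 5, 19),
    cutoff_spec("CDC 5", "CDC", "thinness", -1.64, 2, 20),
    cutoff_spec("CDC 85", "CDC", "overweight", 1.04, 2, 20),
    cutoff_spec("CDC 95", "CDC", "obesity", 1.64, 2, 20)
  )
}

# age membership with older-band preference at shared boundaries
.specs_covering <- function(specs, age) {
  hit <- vapply(specs, function(s)
    age >= s$age_min - 1e-9 && age <= s$age_max + 1e-9, TRUE)
  specs <- specs[hit]
  if (length(specs) > 1L) {
    starts <- vapply(specs, `[[`, 0, "age_min")
    if (any(abs(starts - age) < 1e-9))
      specs <- specs[abs(starts - age) < 1e-9]
  }
  specs
}

#' Resolve a cut-off label to a single age-sex-specific definition
#'
#' `label` may be an exact registry label (`"WHO +1"`) or a
#' `"<reference> <category>"` alias (`"IOTF overweight"`), in which case
#' the age picks the applicable band. A generic `"IOTF thinness"` request
#' resolves to grade 2 (`"IOTF 17"`), the grade closest to the WHO and CDC
#' thinness cut-offs, with a warning that grade 1 (`"IOTF 18.5"`) must be
#' named explicitly if wanted.
#'
#' @param registry A [cutoff_registry()].
#' @param label Cut-off label or reference-category alias.
#' @param sex `"male"` or `"female"` (synonyms accepted).
#' @param age Age in years.
#' @return A `cutoff_spec` with `z` resolved to a single number for `sex`.
#' @examples
#' reg <- default_cutoffs()
#' resolve_cutoff(reg, "IOTF overweight", "male", 8)$z   # 1.31
#' resolve_cutoff(reg, "WHO overweight", "male", 8)$z    # 1
#' resolve_cutoff(reg, "WHO overweight", "male", 4.5)$z  # 2
#' @export
resolve_cutoff <- function(registry, label, sex, age) {
  stopifnot(inherits(registry, "cutoff_registry"),
            is.character(label), length(label) == 1L,
            is.numeric(age), length(age) == 1L)
  sex <- normalize_sex(sex)
  cand <- registry[vapply(registry, function(s) identical(s$label, label), TRUE)]
  if (!length(cand)) {
    # alias form "<reference> <category>"
    parts <- strsplit(trimws(label), "\\s+")[[1]]
    if (length(parts) >= 2L) {
      ref <- parts[1]
      cat_ <- tolower(paste(parts[-1], collapse = " "))
      cand <- registry[vapply(registry, function(s)
        identical(s$reference, ref) && identical(s$category, cat_), TRUE)]
      if (identical(cat_, "thinness") && length(cand) > 1L) {
        grade2 <- cand[vapply(cand, function(s)
          identical(s$label, "IOTF 17"), TRUE)]
        if (length(grade2)) {
          warning(sprintf(
            "'%s' resolved to grade 2 ('IOTF 17'); request 'IOTF 18.5' explicitly for grade 1",
            label))
          cand <- grade2
        }
      }
    }
  }
  if (!length(cand))
    stop(sprintf("unknown cut-off label '%s'", label))
  cand <- .specs_covering(cand, age)
  if (!length(cand))
    stop(sprintf("no '%s' definition covers age %g y", label, age))
  if (length(cand) > 1L)
    stop(sprintf("'%s' is ambiguous at age %g y: %s", label, age,
                 paste(vapply(cand, `[[`, "", "label"), collapse = ", ")))
  spec <- cand[[1]]
  if (length(spec$z) == 2L) {
    if (identical(sex, "both"))
      stop(sprintf("'%s' has sex-specific z values; sex must be male or female",
                   spec$label))
    spec$z <- unname(spec$z[[sex]])
  } else {
    spec$z <- unname(spec$z)
  }
  spec$sex <- sex
  spec
}
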
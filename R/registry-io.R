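# Flat-file serialization of cut-off registries.

#' Read / write a cut-off registry as CSV
#'
#' Schema: `label, reference, category, sex, z, age_min, age_max`, one
#' row per (entry, sex); `sex = "both"` covers both sexes in one row,
#' while `male`/`female` rows sharing label and age range combine into
#' one sex-specific entry.
#'
#' @param path File path.
#' @param registry A [cutoff_registry()].
#' @return The registry (read); `path` invisibly (write).
#' @export
read_cutoffs_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("label", "reference", "category", "sex", "z",
                "age_min", "age_max")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop(sprintf("'%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  raw$sex <- vapply(raw$sex, normalize_sex, "")
  key <- paste(raw$label, raw$category, raw$age_min, raw$age_max, sep = "\r")
  specs <- lapply(unique(key), function(k) {
    rows <- raw[key == k, ]
    z <- if (nrow(rows) == 1L && rows$sex[1] == "both") rows$z[1]
    else {
      if (!setequal(rows$sex, c("male", "female")))
        stop(sprintf("'%s': entry '%s' must have sex 'both' or one 'male' and one 'female' row",
                     path, rows$label[1]))
      c(male = rows$z[rows$sex == "male"],
        female = rows$z[rows$sex == "female"])
    }
    cutoff_spec(rows$label[1], rows$reference[1], rows$category[1], z,
                rows$age_min[1], rows$age_max[1])
  })
  cutoff_registry(specs)
}

#' @rdname read_cutoffs_csv
#' @export
write_cutoffs_csv <- function(registry, path) {
  stopifnot(inherits(registry, "cutoff_registry"))
  rows <- do.call(rbind, lapply(registry, function(s) {
    if (length(s$z) == 1L)
      data.frame(label = s$label, reference = s$reference,
                 category = s$category, sex = "both", z = unname(s$z),
                 age_min = s$age_min, age_max = s$age_max)
    else
      data.frame(label = s$label, reference = s$reference,
                 category = s$category, sex = c("male", "female"),
                 z = unname(s$z[c("male", "female")]),
                 age_min = s$age_min, age_max = s$age_max)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
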
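# Validation of the conversion on paired prevalence data.
#
# Groups of children with prevalence observed under two cut-offs A and B
# give an empirical probit difference dZ = Z_B - Z_A to compare with the
# cut-off distance dz. The probit regression
#     g(p_B) = Z_A + b * dz + error,   g(p) = -sign(z) * qnorm(p)
# has no intercept (which keeps the conversion reversible) and slope b
# defaulting to 1; counts are modelled as beta-binomial with intraclass
# correlation proportional to |dz|, since extrapolation error grows with
# the distance between the cut-offs.

.category_sign <- function(category) {
  ifelse(category == "thinness", -1, 1)
}

.pairs_schema <- c("group", "source", "sex", "mean_age", "n", "category",
                   "cutoff_A", "cutoff_B", "prev_A", "prev_B")

#' Read / write a paired-prevalence dataset CSV
#'
#' Schema: `group, source, sex, mean_age, n, category, cutoff_A,
#' cutoff_B, prev_A, prev_B, overweight_is_net`, with prevalences in
#' percent.
#'
#' @param path File path.
#' @param data Data frame in the schema above.
#' @return The data frame (read); `path` invisibly (write).
#' @export
read_pairs_csv <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.pairs_schema, names(dat))
  if (length(missing_cols))
    stop(sprintf("'%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  if (is.null(dat$overweight_is_net)) dat$overweight_is_net <- FALSE
  dat$overweight_is_net <- as.logical(dat$overweight_is_net)
  dat
}

#' @rdname read_pairs_csv
#' @export
write_pairs_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# add obesity prevalence into net-of-obesity overweight rows, matching the
# obesity row of the same group carrying the same reference pair
.make_overweight_inclusive <- function(dat, registry) {
  net <- which(dat$category == "overweight" & dat$overweight_is_net)
  if (!length(net)) return(dat)
  ref_of <- function(i, side) {
    lab <- dat[[paste0("cutoff_", side)]][i]
    resolve_cutoff(registry, lab, dat$sex[i], dat$mean_age[i])$reference
  }
  for (i in net) {
    rA <- ref_of(i, "A"); rB <- ref_of(i, "B")
    ob <- which(dat$category == "obesity" & dat$group == dat$group[i] &
                  dat$source == dat$source[i])
    hit_same <- hit_swap <- integer()
    for (j in ob) {
      oA <- ref_of(j, "A"); oB <- ref_of(j, "B")
      if (oA == rA && oB == rB) hit_same <- c(hit_same, j)
      else if (oA == rB && oB == rA) hit_swap <- c(hit_swap, j)
    }
    if (length(hit_same) + length(hit_swap) != 1L)
      stop(sprintf("group '%s': need exactly one obesity row for references %s/%s to make overweight inclusive",
                   dat$group[i], rA, rB))
    if (length(hit_same)) {
      dat$prev_A[i] <- dat$prev_A[i] + dat$prev_A[hit_same]
      dat$prev_B[i] <- dat$prev_B[i] + dat$prev_B[hit_same]
    } else {
      dat$prev_A[i] <- dat$prev_A[i] + dat$prev_B[hit_swap]
      dat$prev_B[i] <- dat$prev_B[i] + dat$prev_A[hit_swap]
    }
    dat$overweight_is_net[i] <- FALSE
  }
  dat
}

#' Stack a paired-prevalence dataset into oriented records
#'
#' One record per (group x cut-off pair), with probits, the cut-off
#' distance dz, and the orientation normalized so dz > 0 (records entered
#' the other way round are swapped, which negates dz). Net-of-obesity
#' overweight rows are first made inclusive of obesity using the matching
#' obesity row of the same group. With `orientation = "both"` each record
#' also appears reversed, doubling the row count.
#'
#' @param data Data frame in the [read_pairs_csv()] schema (prevalences
#'   in percent).
#' @param refs Named list of [reference_table()]s (used to compute dz
#'   when `dz_table` is not given).
#' @param registry A [cutoff_registry()].
#' @param dz_table Optional look-up table from [build_lookup_table()];
#'   when supplied, dz comes from [lookup_dz()] at the grid age nearest
#'   each group's mean age.
#' @param orientation `"positive"` (default; one record per pair, dz > 0)
#'   or `"both"`.
#' @return Data frame of class `paired_prevalence` with proportions
#'   `p_A`, `p_B`, probits `Z_A`, `Z_B`, `dZ = Z_B - Z_A` and `dz`.
#' @export
stack_records <- function(data, refs = NULL, registry = default_cutoffs(),
                          dz_table = NULL,
                          orientation = c("positive", "both")) {
  orientation <- match.arg(orientation)
  missing_cols <- setdiff(.pairs_schema, names(data))
  if (length(missing_cols))
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(data$overweight_is_net)) data$overweight_is_net <- FALSE
  dat <- as.data.frame(data)
  dat$sex <- vapply(dat$sex, normalize_sex, "")
  if (any(is.na(dat$prev_A) | is.na(dat$prev_B)))
    stop(sprintf("missing prevalence in row %d",
                 which(is.na(dat$prev_A) | is.na(dat$prev_B))[1]))
  dat <- .make_overweight_inclusive(dat, registry)
  dat <- dat[dat$category %in% c("thinness", "overweight", "obesity"), ]
  if (any(dat$prev_A > 100 + 1e-9 | dat$prev_B > 100 + 1e-9))
    stop("prevalence exceeds 100% after making overweight inclusive")
  n_rec <- nrow(dat)
  dz <- numeric(n_rec)
  for (i in seq_len(n_rec)) {
    specA <- resolve_cutoff(registry, dat$cutoff_A[i], dat$sex[i], dat$mean_age[i])
    specB <- resolve_cutoff(registry, dat$cutoff_B[i], dat$sex[i], dat$mean_age[i])
    if (!identical(specA$category, specB$category))
      stop(sprintf("row %d: cut-offs '%s' and '%s' are in different categories",
                   i, dat$cutoff_A[i], dat$cutoff_B[i]))
    if (!identical(specA$category, dat$category[i]))
      stop(sprintf("row %d: category '%s' does not match cut-off '%s' (%s)",
                   i, dat$category[i], dat$cutoff_A[i], specA$category))
    dz[i] <- if (!is.null(dz_table))
      lookup_dz(dz_table, c(dat$cutoff_A[i], dat$cutoff_B[i]),
                dat$sex[i], dat$mean_age[i])
    else if (!is.null(refs))
      cutoff_distance(dat$cutoff_A[i], dat$cutoff_B[i], dat$sex[i],
                      dat$mean_age[i], refs, registry)$dz
    else stop("supply either 'dz_table' or 'refs' to obtain dz")
  }
  sign <- .category_sign(dat$category)
  rec <- data.frame(group = dat$group, source = dat$source, sex = dat$sex,
                    mean_age = dat$mean_age, n = dat$n,
                    category = dat$category,
                    cutoff_A = dat$cutoff_A, cutoff_B = dat$cutoff_B,
                    p_A = dat$prev_A / 100, p_B = dat$prev_B / 100,
                    dz = dz, stringsAsFactors = FALSE)
  flip <- rec$dz < 0
  if (any(flip)) {
    tmp <- rec[flip, ]
    rec[flip, c("cutoff_A", "cutoff_B")] <- tmp[, c("cutoff_B", "cutoff_A")]
    rec[flip, c("p_A", "p_B")] <- tmp[, c("p_B", "p_A")]
    rec$dz[flip] <- -tmp$dz
  }
  if (identical(orientation, "both")) {
    rev <- rec
    rev[, c("cutoff_A", "cutoff_B")] <- rec[, c("cutoff_B", "cutoff_A")]
    rev[, c("p_A", "p_B")] <- rec[, c("p_B", "p_A")]
    rev$dz <- -rec$dz
    rec <- rbind(rec, rev)
    sign <- c(sign, sign)
    rownames(rec) <- NULL
  }
  rec$Z_A <- -sign * stats::qnorm(.boundary_correct(rec$p_A, rec$n))
  rec$Z_B <- -sign * stats::qnorm(.boundary_correct(rec$p_B, rec$n))
  rec$dZ <- rec$Z_B - rec$Z_A
  class(rec) <- c("paired_prevalence", "data.frame")
  rec
}

.boundary_correct <- function(p, n) {
  at <- p <= 0 | p >= 1
  if (any(at)) {
    if (any(!is.finite(n[at])))
      stop("prevalence 0 or 1 needs a denominator for the continuity correction")
    p[at] <- ifelse(p[at] <= 0, 1 / (2 * n[at]), 1 - 1 / (2 * n[at]))
  }
  p
}

# beta-binomial log-pmf with mean pi and intraclass correlation rho;
# rho ~ 0 collapses to the binomial
.dbetabinom_log <- function(y, n, pi, rho) {
  pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
  out <- numeric(length(y))
  bb <- rho > 1e-10
  if (any(bb)) {
    a <- pi[bb] * (1 - rho[bb]) / rho[bb]
    b <- (1 - pi[bb]) * (1 - rho[bb]) / rho[bb]
    out[bb] <- lchoose(n[bb], y[bb]) + lbeta(y[bb] + a, n[bb] - y[bb] + b) -
      lbeta(a, b)
  }
  if (any(!bb))
    out[!bb] <- stats::dbinom(y[!bb], n[!bb], pi[!bb], log = TRUE)
  out
}

#' Fit the no-intercept probit slope model to stacked records
#'
#' Maximum-likelihood fit of `g(p_B) = Z_A + b * dz` with `Z_A` as offset
#' and `b * dz` the only linear term, to the observed counts
#' `y = round(p_B * n)`. Models: `fixed_b1` evaluates the likelihood at
#' `b = 1`; `common_slope` estimates one b; `grouped_slopes` estimates
#' one b per (source x category) cell. Counts are beta-binomial with
#' intraclass correlation `c * |dz|` (`error_model = "beta_binomial"`,
#' the default; records with dz = 0 collapse to binomial) or plain
#' binomial.
#'
#' @param records A `paired_prevalence` data frame from
#'   [stack_records()] (or the simulators).
#' @param model `"common_slope"`, `"fixed_b1"` or `"grouped_slopes"`.
#' @param error_model `"beta_binomial"` or `"binomial"`.
#' @return An object of class `validation_fit`: slope estimate(s) `b`
#'   with Wald 95% CIs, dispersion coefficient `c_disp`, `logLik`, `BIC`.
#' @export
fit_slope <- function(records,
                      model = c("common_slope", "fixed_b1", "grouped_slopes"),
                      error_model = c("beta_binomial", "binomial")) {
  model <- match.arg(model)
  error_model <- match.arg(error_model)
  if (!nrow(records)) stop("no records to fit")
  if (nrow(records) < 2L && model != "fixed_b1")
    stop("at least 2 records are needed to estimate a slope")
  if (any(abs(records$n - round(records$n)) > 1e-8))
    stop("denominators 'n' must be whole counts")
  n <- round(records$n)
  y <- round(records$p_B * n)
  sign <- .category_sign(records$category)
  dz <- records$dz
  Z_A <- records$Z_A
  if (model != "fixed_b1" && max(abs(dz)) < 1e-8)
    stop("slope is unidentifiable: all records have dz ~ 0")
  cell <- if (model == "grouped_slopes")
    droplevels(interaction(records$source, records$category, sep = " ",
                           drop = TRUE))
  else factor(rep("all", nrow(records)))
  cell_idx <- as.integer(cell)
  nb <- if (model == "fixed_b1") 0L else nlevels(cell)
  disp <- error_model == "beta_binomial" && max(abs(dz)) > 1e-8
  npar <- nb + as.integer(disp)

  nll <- function(par) {
    b <- if (nb) par[seq_len(nb)][cell_idx] else rep(1, length(y))
    rho <- if (disp) pmin(par[npar] * abs(dz), 1 - 1e-8) else rep(0, length(y))
    pi <- stats::pnorm(-sign * (Z_A + b * dz))
    -sum(.dbetabinom_log(y, n, pi, rho))
  }

  if (npar) {
    start <- c(rep(1, nb), if (disp) 0.1)
    lower <- c(rep(-10, nb), if (disp) 1e-9)
    upper <- c(rep(10, nb), if (disp) 0.99 / max(abs(dz)))
    opt <- stats::optim(start, nll, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(factr = 1e7, maxit = 500))
    if (opt$convergence != 0) {
      # line searches can stall on near-degenerate likelihoods; polish
      # with a derivative-free pass from the stalled point
      polish <- if (npar > 1L)
        stats::optim(opt$par, nll, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
      else
        stats::optim(opt$par, nll, method = "Brent",
                     lower = lower, upper = upper)
      if (polish$value <= opt$value) opt <- polish
      opt$par <- pmin(pmax(opt$par, lower), upper)
      if (opt$convergence != 0 && polish$convergence != 0)
        warning("slope optimisation did not fully converge: ", opt$message)
    }
    par <- opt$par
    ll <- -opt$value
    H <- tryCatch(stats::optimHess(par, nll), error = function(e) NULL)
    se <- rep(NA_real_, npar)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) se <- sqrt(pmax(diag(as.matrix(V)), 0))
    }
  } else {
    par <- numeric()
    ll <- -nll(par)
    se <- numeric()
  }

  if (nb) {
    b <- stats::setNames(par[seq_len(nb)], levels(cell))
    se_b <- stats::setNames(se[seq_len(nb)], levels(cell))
    ci <- cbind(lower = b - 1.96 * se_b, upper = b + 1.96 * se_b)
  } else {
    b <- c(all = 1)
    se_b <- c(all = NA_real_)
    ci <- cbind(lower = NA_real_, upper = NA_real_)
    rownames(ci) <- "all"
  }
  structure(list(
    model = model, error_model = error_model,
    b = b, se_b = se_b, ci = ci,
    c_disp = if (disp) par[npar] else 0,
    se_c = if (disp) se[npar] else NA_real_,
    logLik = ll, BIC = -2 * ll + npar * log(nrow(records)),
    n_records = nrow(records),
    cell_records = as.integer(table(cell)),
    cell_n = as.numeric(tapply(n, cell, sum)),
    cells = levels(cell)), class = "validation_fit")
}

#' @export
print.validation_fit <- function(x, ...) {
  cat(sprintf("<validation_fit> model '%s', %s errors, %d records\n",
              x$model, x$error_model, x$n_records))
  for (i in seq_along(x$b)) {
    if (x$model == "fixed_b1")
      cat("  b = 1 (fixed)\n")
    else
      cat(sprintf("  b[%s] = %.2f (95%% CI %.2f-%.2f)\n", names(x$b)[i],
                  x$b[i], x$ci[i, 1], x$ci[i, 2]))
  }
  if (x$error_model == "beta_binomial")
    cat(sprintf("  dispersion: rho = %.4g * |dz|\n", x$c_disp))
  cat(sprintf("  logLik = %.1f, BIC = %.1f\n", x$logLik, x$BIC))
  invisible(x)
}

#' Average the cell slopes of a grouped fit
#'
#' Collapses the per-(source x category) slopes of a `grouped_slopes` fit
#' into a single slope multiplier. The default equal weighting values
#' each data source and category the same regardless of size; weighting
#' by record count or by total denominator is also available.
#'
#' @param fit A `validation_fit` from [fit_slope()] with
#'   `model = "grouped_slopes"` (any fit works; a single slope is
#'   returned unchanged).
#' @param weights `"equal"`, `"records"` or `"denominator"`.
#' @return A single slope value.
#' @examples
#' # equal-weight mean of published per-cell slopes:
#' mean(c(1.02, 0.96, 0.82, 0.74, 0.68))  # 0.84
#' @export
average_slope <- function(fit, weights = c("equal", "records", "denominator")) {
  weights <- match.arg(weights)
  w <- switch(weights,
              equal = rep(1, length(fit$b)),
              records = fit$cell_records,
              denominator = fit$cell_n)
  sum(fit$b * w) / sum(w)
}

#' Percentage of baseline variance explained
#'
#' `100 * (1 - (rsd / baseline_sd)^2)`: how much of the variance of the
#' raw prevalence difference between two cut-offs the conversion removes.
#'
#' @param rsd Residual SD of observed minus predicted prevalence.
#' @param baseline_sd SD of the raw difference `p_A - p_B`.
#' @return Percent of variance explained.
#' @examples
#' variance_explained(3, 6)  # 75
#' @export
variance_explained <- function(rsd, baseline_sd) {
  100 * (1 - (rsd / baseline_sd)^2)
}

# predictions in both directions; returns percent-scale residual frames
.predict_both <- function(records, b) {
  sign <- .category_sign(records$category)
  phat_B <- stats::pnorm(-sign * (records$Z_A + b * records$dz))
  phat_A <- stats::pnorm(-sign * (records$Z_B - b * records$dz))
  list(phat_A = phat_A, phat_B = phat_B, sign = sign)
}

#' Residual summary of the conversion on stacked records
#'
#' Predicts each prevalence from its partner in both directions with
#' slope multiplier `b`, and summarizes the residuals
#' (observed - predicted, percent scale) per category and overall:
#' residual SD, the baseline SD of the raw difference `p_A - p_B`
#' (both orientations), and the percentage of baseline variance
#' explained. Also reports the z-score-scale residual SD.
#'
#' @param records A `paired_prevalence` data frame.
#' @param b Slope multiplier applied to dz (1 = plain algorithm).
#' @return An object of class `residual_summary` whose `table` element
#'   has one row per category plus `"all"`.
#' @export
residual_summary <- function(records, b = 1) {
  if (!nrow(records)) stop("no records to summarize")
  pr <- .predict_both(records, b)
  res <- 100 * c(records$p_A - pr$phat_A, records$p_B - pr$phat_B)
  base <- 100 * c(records$p_A - records$p_B, records$p_B - records$p_A)
  cat2 <- rep(records$category, 2)
  lvls <- c(intersect(c("obesity", "overweight", "thinness"), unique(cat2)),
            "all")
  one <- function(keep) {
    r <- res[keep]; d <- base[keep]
    c(n = sum(keep), rsd = stats::sd(r), baseline_sd = stats::sd(d),
      variance_explained = variance_explained(stats::sd(r), stats::sd(d)))
  }
  rows <- t(vapply(lvls, function(l)
    one(if (l == "all") rep(TRUE, length(res)) else cat2 == l),
    numeric(4)))
  eps_z <- records$Z_B - (records$Z_A + b * records$dz)
  structure(list(
    table = data.frame(category = lvls, rows, row.names = NULL),
    rsd_z = sqrt(mean(eps_z^2)), b = b), class = "residual_summary")
}

#' @export
print.residual_summary <- function(x, ...) {
  cat(sprintf("<residual_summary> b = %g\n", x$b))
  tab <- x$table
  tab$rsd <- round(tab$rsd, 2)
  tab$baseline_sd <- round(tab$baseline_sd, 2)
  tab$variance_explained <- round(tab$variance_explained, 1)
  print(tab, row.names = FALSE)
  cat(sprintf("  z-scale RSD = %.3f\n", x$rsd_z))
  invisible(x)
}

#' Bland-Altman pairs for observed vs predicted prevalence
#'
#' For each record and direction, the mean of observed and predicted
#' prevalence against their difference (`type = "algorithm"`); plus the
#' baseline pairs `((p_A + p_B)/2, +/-(p_A - p_B))` comparing the raw
#' prevalences (`type = "baseline"`). Percent scale.
#'
#' @inheritParams residual_summary
#' @return Data frame with columns `mean`, `diff`, `category`, `source`,
#'   `type`.
#' @export
bland_altman <- function(records, b = 1) {
  pr <- .predict_both(records, b)
  alg <- data.frame(
    mean = 100 * c((records$p_A + pr$phat_A) / 2,
                   (records$p_B + pr$phat_B) / 2),
    diff = 100 * c(records$p_A - pr$phat_A, records$p_B - pr$phat_B),
    category = rep(records$category, 2), source = rep(records$source, 2),
    type = "algorithm", stringsAsFactors = FALSE)
  base <- data.frame(
    mean = 100 * rep((records$p_A + records$p_B) / 2, 2),
    diff = 100 * c(records$p_A - records$p_B, records$p_B - records$p_A),
    category = rep(records$category, 2), source = rep(records$source, 2),
    type = "baseline", stringsAsFactors = FALSE)
  rbind(alg, base)
}
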
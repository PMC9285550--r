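# Synthetic LMS references and grouped prevalence datasets.
#
# The population model lives in the z-metric of a chosen base reference:
# a child's z-score is N(z_shift, s_inflation^2). With s_inflation = 1
# the population differs from the references by a pure z-score shift --
# the exact situation the conversion assumes -- and every simulated
# prevalence has a closed-form tail probability. s_inflation > 1 gives
# the population heavier tails than the reference, the documented
# mechanism by which the validation slope drops below 1.

# run expr under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single numeric 'seed' is required")
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

.eval_curve <- function(curve, age, what) {
  if (is.function(curve)) return(curve(age))
  if (is.numeric(curve))  # polynomial coefficients, intercept first
    return(drop(outer(age, seq_along(curve) - 1, `^`) %*% curve))
  stop(sprintf("'%s' must be a coefficient vector or a function of age", what))
}

#' Generate a synthetic growth-reference table
#'
#' Builds a [reference_table()] on an age grid from smooth parametric
#' curves for L, M and S: each is a vector of polynomial coefficients in
#' age (intercept first), a `function(age)`, or a list with `male` and
#' `female` components of either form. Fully deterministic.
#'
#' @param name Reference name.
#' @param L,M,S Parameter curves (see Details above).
#' @param ages Age grid, years; default half-years 2 to 18.
#' @return A [reference_table()].
#' @examples
#' make_reference("flat", L = 1, M = 20, S = 0.1)      # constant rows
#' make_reference("lin", L = 0, M = c(14, 0.4), S = 0.1) # M = 14 + 0.4*age
#' @export
make_reference <- function(name, L, M, S, ages = seq(2, 18, by = 0.5)) {
  per_sex <- function(curve, sex, what) {
    if (is.list(curve) && !is.function(curve)) {
      if (!all(c("male", "female") %in% names(curve)))
        stop(sprintf("list-valued '%s' needs 'male' and 'female' components", what))
      curve <- curve[[sex]]
    }
    .eval_curve(curve, ages, what)
  }
  rows <- do.call(rbind, lapply(c("male", "female"), function(sx)
    data.frame(sex = sx, age = ages,
               L = per_sex(L, sx, "L"), M = per_sex(M, sx, "M"),
               S = per_sex(S, sx, "S"))))
  if (any(rows$S <= 0)) stop("'S' curve is non-positive within the age span")
  if (any(rows$M <= 0)) stop("'M' curve is non-positive within the age span")
  reference_table(name, rows)
}

#' Synthetic reference library for testing and examples
#'
#' Three BMI-like references on half-year ages 2-18, all in the L = 0
#' (log-normal) LMS family with a realistic median curve (dipping near
#' age 5, rising to ~22 kg/m^2 at 18) and coefficient of variation
#' rising from ~9% to ~14% with age:
#' * `refA` -- the base reference;
#' * `refB` -- identical shape, median scaled so that `refB` differs from
#'   `refA` by an exact age-dependent z-score shift (0.51 falling to 0.19
#'   across the age span, mirroring how reference cut-off distances
#'   shrink with age). Against `refA` the shift assumption holds exactly;
#' * `refC` -- same median as `refA` but S inflated by 15%, so cut-off
#'   distances against `refA` grow with the cut-off z (obesity further
#'   than overweight).
#'
#' @return Named list of three [reference_table()]s.
#' @seealso [synthetic_cutoffs()] for matching cut-off definitions.
#' @export
synthetic_references <- function() {
  S_A <- c(0.085, 0.003)
  M_A <- c(16.8, -0.55, 0.047)
  M_fun_A <- function(age) .eval_curve(M_A, age, "M")
  S_fun_A <- function(age) .eval_curve(S_A, age, "S")
  delta <- function(age) 0.55 - 0.02 * age
  list(
    refA = make_reference("refA", L = 0, M = M_A, S = S_A),
    refB = make_reference("refB", L = 0,
                          M = function(age) M_fun_A(age) *
                            exp(S_fun_A(age) * delta(age)),
                          S = S_A),
    refC = make_reference("refC", L = 0, M = M_A,
                          S = function(age) 1.15 * S_fun_A(age)))
}

#' Cut-off registry for the synthetic references
#'
#' Thinness/overweight/obesity z-score cut-offs for the three synthetic
#' references, echoing the spread of the real definitions: `refA` uses
#' -2/+1/+2, `refB` -1.9/+1.3/+2.3, `refC` -1.64/+1.04/+1.64.
#'
#' @return A [cutoff_registry()].
#' @export
synthetic_cutoffs <- function() {
  mk <- function(ref, z_thin, z_ow, z_ob) list(
    cutoff_spec(sprintf("%s %+g", ref, z_thin), ref, "thinness", z_thin, 2, 18),
    cutoff_spec(sprintf("%s %+g", ref, z_ow), ref, "overweight", z_ow, 2, 18),
    cutoff_spec(sprintf("%s %+g", ref, z_ob), ref, "obesity", z_ob, 2, 18))
  cutoff_registry(c(mk("refA", -2, 1, 2),
                    mk("refB", -1.9, 1.3, 2.3),
                    mk("refC", -1.64, 1.04, 1.64)))
}

# group-level true tail probability in the base reference's z-metric
.true_prevalence <- function(z_cut_base, sign, z_shift, s_inflation) {
  stats::pnorm(-sign * (z_cut_base - z_shift) / s_inflation)
}

.default_groups <- function(n_groups = 24, n_per_group = 1000) {
  data.frame(sex = rep(c("male", "female"), length.out = n_groups),
             mean_age = rep(seq(6, 16, length.out = ceiling(n_groups / 2)),
                            each = 2)[seq_len(n_groups)],
             n = n_per_group)
}

#' Simulate a grouped prevalence dataset under the shift model
#'
#' For each group and cut-off pair, the true exceedance probability is
#' the exact tail area of the shifted (and optionally S-inflated)
#' population beyond the cut-off, evaluated in the base reference's
#' z-metric with the cut-off re-expressed via [cross_z()]; observed
#' counts are drawn binomially. With `s_inflation = 1` the simulated
#' data satisfy the shift assumption exactly, so the probit difference
#' dZ equals dz in expectation; `s_inflation > 1` gives the population
#' heavier tails and attenuates the recoverable slope below 1.
#'
#' @param groups Data frame with columns `sex`, `mean_age`, `n`.
#' @param refs Named list of [reference_table()]s (e.g.
#'   [synthetic_references()]).
#' @param registry A [cutoff_registry()] (e.g. [synthetic_cutoffs()]).
#' @param pairs Cut-off pairs (`"A:B"` strings or length-2 vectors).
#' @param base_reference Name of the reference defining the population's
#'   z-metric.
#' @param z_shift Population shift on the z-score scale.
#' @param s_inflation Multiplicative spread factor (1 = assumption holds).
#' @param seed Mandatory RNG seed; identical seeds give identical output.
#' @param source Value for the `source` column.
#' @param return_truth Also return the analytic prevalences as
#'   `true_prev_A`/`true_prev_B` columns (percent)?
#' @return Data frame in the [read_pairs_csv()] schema (percent).
#' @export
simulate_prevalence_dataset <- function(groups, refs, registry, pairs,
                                        base_reference = names(refs)[1],
                                        z_shift = 0, s_inflation = 1,
                                        seed, source = "synthetic",
                                        return_truth = FALSE) {
  stopifnot(all(c("sex", "mean_age", "n") %in% names(groups)),
            all(groups$n >= 1), s_inflation > 0)
  pairs <- .parse_pairs(pairs)
  base <- refs[[base_reference]]
  if (is.null(base)) stop(sprintf("base reference '%s' not in 'refs'",
                                  base_reference))
  .with_seed(seed, {
    rows <- list()
    for (g in seq_len(nrow(groups))) for (p in pairs) {
      sx <- normalize_sex(groups$sex[g])
      age <- groups$mean_age[g]
      n <- round(groups$n[g])
      A <- resolve_cutoff(registry, p[1], sx, age)
      B <- resolve_cutoff(registry, p[2], sx, age)
      if (!identical(A$category, B$category))
        stop(sprintf("pair %s:%s mixes categories", p[1], p[2]))
      sign <- A$sign
      pA <- .true_prevalence(cross_z(A, base, sx, age, refs), sign,
                             z_shift, s_inflation)
      pB <- .true_prevalence(cross_z(B, base, sx, age, refs), sign,
                             z_shift, s_inflation)
      clamped <- c(pA, pB) <= 0 | c(pA, pB) >= 1
      if (any(clamped))
        warning(sprintf("group %d pair %s:%s: tail probability at machine boundary, clamped",
                        g, p[1], p[2]))
      pA <- min(max(pA, 1e-12), 1 - 1e-12)
      pB <- min(max(pB, 1e-12), 1 - 1e-12)
      rows[[length(rows) + 1L]] <- data.frame(
        group = sprintf("g%03d", g), source = source, sex = sx,
        mean_age = age, n = n, category = A$category,
        cutoff_A = A$label, cutoff_B = B$label,
        prev_A = 100 * stats::rbinom(1, n, pA) / n,
        prev_B = 100 * stats::rbinom(1, n, pB) / n,
        overweight_is_net = FALSE,
        true_prev_A = 100 * pA, true_prev_B = 100 * pB,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (!return_truth) out$true_prev_A <- out$true_prev_B <- NULL
    out
  })
}

#' Simulate paired prevalences with a known validation slope
#'
#' Generates data exactly under the validation regression: each group
#' draws a population z-shift, the prevalence beyond cut-off A follows
#' from it, and the partner prevalence satisfies
#' `g(p_B) = Z_A + b_true * dz` before sampling. Counts for B are
#' beta-binomial with intraclass correlation `c_disp * |dz|` (binomial
#' when `c_disp = 0`), matching the error model of [fit_slope()], so the
#' fitted slope is a direct parameter-recovery check.
#'
#' @inheritParams simulate_prevalence_dataset
#' @param b_true True slope multiplier on dz.
#' @param c_disp Dispersion coefficient (intraclass correlation per unit
#'   |dz|).
#' @param z_shift_mean,z_shift_sd Distribution of the per-group
#'   population shift.
#' @return Data frame in the [read_pairs_csv()] schema (percent).
#' @export
simulate_slope_dataset <- function(b_true, groups, refs, registry, pairs,
                                   base_reference = names(refs)[1],
                                   c_disp = 0, z_shift_mean = 0,
                                   z_shift_sd = 0.3, seed,
                                   source = "synthetic") {
  stopifnot(is.numeric(b_true), length(b_true) == 1L, c_disp >= 0)
  pairs <- .parse_pairs(pairs)
  base <- refs[[base_reference]]
  if (is.null(base)) stop(sprintf("base reference '%s' not in 'refs'",
                                  base_reference))
  .with_seed(seed, {
    shifts <- stats::rnorm(nrow(groups), z_shift_mean, z_shift_sd)
    rows <- list()
    for (g in seq_len(nrow(groups))) for (p in pairs) {
      sx <- normalize_sex(groups$sex[g])
      age <- groups$mean_age[g]
      n <- round(groups$n[g])
      A <- resolve_cutoff(registry, p[1], sx, age)
      sign <- A$sign
      d <- cutoff_distance(p[1], p[2], sx, age, refs, registry)
      Z_A_true <- cross_z(A, base, sx, age, refs) - shifts[g]
      pA <- stats::pnorm(-sign * Z_A_true)
      pB <- stats::pnorm(-sign * (Z_A_true + b_true * d$dz))
      yA <- stats::rbinom(1, n, pA)
      rho <- min(c_disp * abs(d$dz), 1 - 1e-8)
      yB <- if (rho > 1e-10) {
        pi_g <- stats::rbeta(1, pB * (1 - rho) / rho,
                             (1 - pB) * (1 - rho) / rho)
        stats::rbinom(1, n, pi_g)
      } else stats::rbinom(1, n, pB)
      rows[[length(rows) + 1L]] <- data.frame(
        group = sprintf("g%03d", g), source = source, sex = sx,
        mean_age = age, n = n, category = A$category,
        cutoff_A = A$label, cutoff_B = p[2],
        prev_A = 100 * yA / n, prev_B = 100 * yB / n,
        overweight_is_net = FALSE, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' The boys-aged-8 overweight worked example
#'
#' The published illustration of the conversion: overweight (including
#' obesity) in boys aged 8 under the WHO +1 and IOTF 25 cut-offs. The
#' WHO cut-off is z = 1.00 on its own reference and 0.91 scored on IOTF;
#' the IOTF cut-off is z = 1.31 on its own reference and 1.47 scored on
#' WHO, giving dz = 0.435 (printed as 1.39 - 0.96 = 0.43). The target
#' group of Ukrainian boys observed 29.3% (WHO) and 18.0% (IOTF).
#'
#' @return A list with the four z-scores, the `cutoff_distance` object,
#'   and the observed prevalences `p_A` (WHO) and `p_B` (IOTF) as
#'   proportions.
#' @export
worked_example_fixture <- function() {
  d <- .new_cutoff_distance("WHO +1", "IOTF 25", sex = "male", age = 8,
                            z_A = 1.00, z_B = 1.31,
                            z_A_onB = 0.91, z_B_onA = 1.47,
                            category = "overweight")
  list(sex = "male", age = 8, category = "overweight",
       label_A = "WHO +1", label_B = "IOTF 25",
       z_A = 1.00, z_B = 1.31, z_A_onB = 0.91, z_B_onA = 1.47,
       p_A = 0.293, p_B = 0.180, distance = d)
}
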
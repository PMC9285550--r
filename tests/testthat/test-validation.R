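# Stacking, the probit slope regression and residual summaries.

test_that("a two-source design stacks to the expected record counts", {
  # 52 groups x 2 pairs (overweight + obesity between two references)
  src1 <- simulate_prevalence_dataset(
    make_groups(52, 1500, ages = seq(6, 9, length.out = 26)),
    test_refs, test_registry, c(ow_pairs[1], ob_pairs[1]),
    z_shift = 0.3, seed = 101, source = "survey1")
  # 22 groups x 9 pairs (three pairs in each of three categories)
  src2 <- simulate_prevalence_dataset(
    make_groups(22, 900, ages = seq(7, 17, length.out = 11)),
    test_refs, test_registry, c(ow_pairs, ob_pairs, thin_pairs),
    z_shift = 0.1, seed = 102, source = "survey2")
  dat <- rbind(src1, src2)
  expect_equal(nrow(dat), 52 * 2 + 22 * 9)
  recs <- stack_records(dat, refs = test_refs, registry = test_registry)
  expect_equal(nrow(recs), 302)
  expect_true(all(recs$dz > 0))
  both <- stack_records(dat, refs = test_refs, registry = test_registry,
                        orientation = "both")
  expect_equal(nrow(both), 604)
  expect_equal(sum(both$dz > 0), sum(both$dz < 0))
})

test_that("records entered against the dz orientation are swapped", {
  dat <- simulate_prevalence_dataset(make_groups(4), test_refs,
                                     test_registry, ow_pairs[1],
                                     z_shift = 0.2, seed = 5)
  flipped <- dat
  flipped[, c("cutoff_A", "cutoff_B")] <- dat[, c("cutoff_B", "cutoff_A")]
  flipped[, c("prev_A", "prev_B")] <- dat[, c("prev_B", "prev_A")]
  r1 <- stack_records(dat, refs = test_refs, registry = test_registry)
  r2 <- stack_records(flipped, refs = test_refs, registry = test_registry)
  expect_equal(r2$p_A, r1$p_A)
  expect_equal(r2$cutoff_A, r1$cutoff_A)
  expect_equal(r2$dz, r1$dz)
  expect_equal(r2$dZ, r1$dZ, tolerance = 1e-12)
})

test_that("net overweight is made inclusive from the matching obesity row", {
  base <- data.frame(group = "g1", source = "s", sex = "male", mean_age = 8,
                     n = 1000, stringsAsFactors = FALSE)
  dat <- rbind(
    cbind(base, category = "overweight", cutoff_A = "refA +1",
          cutoff_B = "refB +1.3", prev_A = 20, prev_B = 12,
          overweight_is_net = TRUE),
    cbind(base, category = "obesity", cutoff_A = "refA +2",
          cutoff_B = "refB +2.3", prev_A = 6, prev_B = 3,
          overweight_is_net = FALSE))
  recs <- stack_records(dat, refs = test_refs, registry = test_registry)
  ow <- recs[recs$category == "overweight", ]
  expect_equal(ow$p_A, 0.26)
  expect_equal(ow$p_B, 0.15)
  # the obesity row may also be entered with the references swapped
  dat2 <- dat
  dat2[2, c("cutoff_A", "cutoff_B")] <- c("refB +2.3", "refA +2")
  dat2[2, c("prev_A", "prev_B")] <- c(3, 6)
  recs2 <- stack_records(dat2, refs = test_refs, registry = test_registry)
  expect_equal(recs2[recs2$category == "overweight", ]$p_A, 0.26)
  # absent obesity row is an error, as is an impossible total
  expect_error(stack_records(dat[1, ], refs = test_refs,
                             registry = test_registry), "obesity row")
  dat3 <- dat; dat3$prev_A[2] <- 85
  expect_error(stack_records(dat3, refs = test_refs,
                             registry = test_registry), "exceeds 100")
})

test_that("noise-free records on the conversion line give b = 1", {
  recs <- exact_records()
  fit <- fit_slope(recs, model = "common_slope")
  expect_equal(unname(fit$b), 1, tolerance = 1e-3)
  # and the fixed-slope model fits them equally well
  fit1 <- fit_slope(recs, model = "fixed_b1")
  expect_lte(fit1$BIC, fit$BIC + log(nrow(recs)))
})

test_that("the slope of beta-binomial data is recovered within its CI", {
  dat <- simulate_slope_dataset(0.78, make_groups(300, 1300), test_refs,
                                test_registry, shift_pairs,
                                c_disp = 0.02, seed = 11)
  recs <- stack_records(dat, refs = test_refs, registry = test_registry)
  fit <- fit_slope(recs, model = "common_slope")
  expect_gt(0.78, fit$ci[1, "lower"])
  expect_lt(0.78, fit$ci[1, "upper"])
  expect_equal(unname(fit$b), 0.78, tolerance = 0.05)
  expect_equal(fit$c_disp, 0.02, tolerance = 0.5)
})

test_that("grouped slopes separate sources with different biases", {
  d1 <- simulate_slope_dataset(1.0, make_groups(80, 2000), test_refs,
                               test_registry, c(ow_pairs[1], ob_pairs[1]),
                               seed = 21, source = "unbiased")
  d2 <- simulate_slope_dataset(0.7, make_groups(80, 2000), test_refs,
                               test_registry, c(ow_pairs[1], ob_pairs[1]),
                               seed = 22, source = "biased")
  recs <- stack_records(rbind(d1, d2), refs = test_refs,
                        registry = test_registry)
  fit <- fit_slope(recs, model = "grouped_slopes")
  expect_equal(length(fit$b), 4)  # 2 sources x 2 categories
  bias_cells <- grepl("^biased", names(fit$b))
  expect_equal(unname(fit$b[bias_cells]), rep(0.7, 2), tolerance = 0.06)
  expect_equal(unname(fit$b[!bias_cells]), rep(1.0, 2), tolerance = 0.06)
  # equal-weight averaging sits between the two truths
  expect_equal(average_slope(fit), 0.85, tolerance = 0.05)
  expect_true(is.finite(average_slope(fit, "records")))
  expect_true(is.finite(average_slope(fit, "denominator")))
})

test_that("model selection prefers the estimated slope when b != 1", {
  dat <- simulate_slope_dataset(0.8, make_groups(150, 2000), test_refs,
                                test_registry, shift_pairs, seed = 31)
  recs <- stack_records(dat, refs = test_refs, registry = test_registry)
  fit1 <- fit_slope(recs, model = "fixed_b1")
  fit2 <- fit_slope(recs, model = "common_slope")
  expect_lte(fit2$BIC, fit1$BIC)
})

test_that("slope estimates are unbiased over replicates", {
  for (truth in c(0.7, 0.85, 1.0)) {
    est <- vapply(1:20, function(rep) {
      dat <- simulate_slope_dataset(truth, make_groups(100, 1500),
                                    test_refs, test_registry, shift_pairs,
                                    seed = 1000 * truth + rep)
      unname(fit_slope(stack_records(dat, refs = test_refs,
                                     registry = test_registry),
                       model = "common_slope",
                       error_model = "binomial")$b)
    }, 0)
    expect_equal(mean(est), truth, tolerance = 0.02)
  }
})

test_that("fit_slope rejects degenerate inputs", {
  recs <- exact_records(n_groups = 4)
  expect_error(fit_slope(recs[0, ]), "no records")
  bad <- recs; bad$n <- bad$n + 0.5
  expect_error(fit_slope(bad), "whole counts")
  same <- recs; same$dz <- 0
  expect_error(fit_slope(same, model = "common_slope"), "unidentifiable")
})

test_that("residual summaries behave at the exact and baseline extremes", {
  recs <- exact_records(n_groups = 10)
  perfect <- residual_summary(recs, b = 1)
  overall <- perfect$table[perfect$table$category == "all", ]
  expect_lt(overall$rsd, 1e-6)
  expect_equal(overall$variance_explained, 100, tolerance = 1e-6)
  # b = 0 predicts each prevalence by its partner: the baseline model
  baseline <- residual_summary(recs, b = 0)
  tab <- baseline$table[baseline$table$category == "all", ]
  expect_equal(tab$rsd, tab$baseline_sd, tolerance = 1e-12)
  expect_equal(tab$variance_explained, 0, tolerance = 1e-9)
  expect_error(residual_summary(recs[0, ]), "no records")
})

test_that("variance_explained evaluates its defining formula", {
  expect_equal(variance_explained(3, 6), 75)
  expect_equal(variance_explained(0, 5), 100)
  expect_equal(variance_explained(5, 5), 0)
})

test_that("variance explained is invariant to relabeling the pair", {
  dat <- simulate_prevalence_dataset(make_groups(20), test_refs,
                                     test_registry, shift_pairs,
                                     z_shift = 0.2, seed = 41)
  recs <- stack_records(dat, refs = test_refs, registry = test_registry)
  swapped <- recs
  swapped[, c("p_A", "p_B")] <- recs[, c("p_B", "p_A")]
  swapped[, c("Z_A", "Z_B")] <- recs[, c("Z_B", "Z_A")]
  swapped$dz <- -recs$dz
  swapped$dZ <- -recs$dZ
  s1 <- residual_summary(recs, b = 1)
  s2 <- residual_summary(swapped, b = 1)
  expect_equal(s1$table$variance_explained, s2$table$variance_explained,
               tolerance = 1e-9)
})

test_that("bland_altman pairs expose the residual structure", {
  recs <- exact_records(n_groups = 10)
  ba <- bland_altman(recs, b = 1)
  alg <- ba[ba$type == "algorithm", ]
  expect_lt(max(abs(alg$diff)), 1e-4)
  base <- ba[ba$type == "baseline", ]
  expect_equal(sort(base$diff), sort(-base$diff), tolerance = 1e-12)
  # with a heavier-tailed population the b-adjusted residuals shrink
  dat <- simulate_prevalence_dataset(make_groups(40, 4000), test_refs,
                                     test_registry,
                                     c(ow_pairs[1], ob_pairs[1]),
                                     z_shift = 0.2, s_inflation = 1.25,
                                     seed = 51)
  hr <- stack_records(dat, refs = test_refs, registry = test_registry)
  b_hat <- unname(fit_slope(hr, model = "common_slope")$b)
  raw <- bland_altman(hr, b = 1)
  adj <- bland_altman(hr, b = b_hat)
  expect_lt(sd(adj$diff[adj$type == "algorithm"]),
            sd(raw$diff[raw$type == "algorithm"]))
})
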
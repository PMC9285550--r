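# Box-Cox (LMS) transforms, interpolation and reference-table I/O.

test_that("z_from_bmi evaluates both branches correctly", {
  # the median maps to z = 0 whatever the shape parameters
  for (L in c(-3, -1.6, 0, 1e-9, 1, 3))
    expect_equal(z_from_bmi(17.3, L, 17.3, 0.12), 0)
  # L = 1 reduces to (x - M)/(M*S)
  expect_equal(z_from_bmi(22, 1, 20, 0.1), 1)
  # log branch agrees with the log-normal distribution function
  x <- c(14, 18, 24.2, 31)
  expect_equal(pnorm(z_from_bmi(x, 0, 20, 0.12)),
               plnorm(x, log(20), 0.12), tolerance = 1e-12)
  expect_equal(z_from_bmi(24.2, 0, 20, 0.12), log(1.21) / 0.12)
  expect_error(z_from_bmi(-1, 0, 20, 0.1), "positive")
  expect_error(z_from_bmi(20, 0, -20, 0.1), "positive")
  expect_error(z_from_bmi(20, 0, 20, 0), "positive")
})

test_that("bmi_from_z inverts z_from_bmi and matches a root-finding oracle", {
  # independent oracle: numerically invert the forward transform
  by_root <- function(z, L, M, S)
    uniroot(function(x) z_from_bmi(x, L, M, S) - z,
            interval = c(1e-3, 1e3), tol = 1e-12)$root
  expect_equal(bmi_from_z(1, -1.6, 16, 0.11), by_root(1, -1.6, 16, 0.11),
               tolerance = 1e-9)
  expect_equal(bmi_from_z(1, -1.6, 16, 0.11), 18.0579, tolerance = 1e-4)
  expect_equal(bmi_from_z(0, -1.6, 16, 0.11), 16)
  grid <- expand.grid(L = c(-3, -1.6, 0, 1, 3), M = c(12, 20, 30),
                      S = c(0.05, 0.12, 0.2), z = seq(-3, 3, by = 0.5))
  ok <- with(grid, abs(L) < 1e-7 | 1 + L * S * z > 1e-6)
  grid <- grid[ok, ]
  x <- with(grid, bmi_from_z(z, L, M, S))
  expect_equal(with(grid, z_from_bmi(x, L, M, S)), grid$z, tolerance = 1e-9)
  for (x0 in c(14, 18, 25, 32))
    expect_equal(bmi_from_z(z_from_bmi(x0, -1.3, 19, 0.13), -1.3, 19, 0.13),
                 x0, tolerance = 1e-9)
  expect_error(bmi_from_z(-8, 1, 20, 0.2), "support")
})

test_that("z_from_bmi is strictly increasing in the measurement", {
  x <- seq(10, 40, by = 0.1)
  for (L in c(-2.5, -0.5, 0, 0.8, 2))
    expect_true(all(diff(z_from_bmi(x, L, 18, 0.12)) > 0))
})

test_that("the power branch converges to the log branch as L -> 0", {
  # the branch gap is L*log(x/M)^2/(2S) to first order, so it shrinks
  # linearly in L and is below 1e-6 near the median at L = 1e-5
  x <- c(13, 17, 22, 30)
  gap <- function(L) max(abs(z_from_bmi(x, L, 18, 0.1) -
                               z_from_bmi(x, 0, 18, 0.1)))
  expect_lt(gap(1e-5), 2e-5)
  expect_lt(gap(1e-6), 2e-6)
  expect_gt(gap(1e-5) / gap(1e-6), 8)  # linear order
  expect_lt(max(abs(z_from_bmi(c(16.5, 18, 19.5), 1e-5, 18, 0.1) -
                      z_from_bmi(c(16.5, 18, 19.5), 0, 18, 0.1))), 1e-6)
  # below the switch the log branch is used exactly
  expect_identical(z_from_bmi(x, 1e-8, 18, 0.1), z_from_bmi(x, 0, 18, 0.1))
  expect_lt(max(abs(bmi_from_z(c(-2, 1, 2), 1e-5, 18, 0.1) -
                      bmi_from_z(c(-2, 1, 2), 0, 18, 0.1))), 1e-4)
})

test_that("tail area above a back-transformed cut-off equals pnorm(-z)", {
  # the BMI density implied by the LMS transform: phi(z(x)) * dz/dx
  lms_density <- function(x, L, M, S) {
    dzdx <- if (abs(L) > 1e-7) (x / M)^(L - 1) / (M * S) else 1 / (x * S)
    dnorm(z_from_bmi(x, L, M, S)) * dzdx
  }
  cases <- list(c(L = -1.6, M = 16, S = 0.11), c(L = 0, M = 18, S = 0.12),
                c(L = 1.2, M = 20, S = 0.08))
  for (cs in cases) for (z in c(-1.5, 0, 1, 2)) {
    cut <- bmi_from_z(z, cs["L"], cs["M"], cs["S"])
    area <- integrate(lms_density, cut, Inf, L = cs[["L"]], M = cs[["M"]],
                      S = cs[["S"]], rel.tol = 1e-10)$value
    expect_equal(area, pnorm(-z), tolerance = 1e-6)
  }
})

test_that("lms_at interpolates linearly and refuses extrapolation", {
  tab <- reference_table("toy", data.frame(
    sex = "both", age = c(4, 5, 6), L = c(-1, -1.2, -1.4),
    M = c(17.0, 17.4, 18.0), S = c(0.10, 0.11, 0.12)))
  at5 <- lms_at(tab, "male", 5)
  expect_equal(c(at5$L, at5$M, at5$S), c(-1.2, 17.4, 0.11))
  expect_equal(lms_at(tab, "female", 4.5)$M, 17.2)
  expect_equal(lms_at(tab, "male", 4.5)$L, -1.1)
  expect_error(lms_at(tab, "male", 7), "span")
  expect_error(lms_at(tab, "dolphin", 5), "unknown sex")
  # a linear generating curve is reproduced exactly anywhere in the span
  lin <- make_reference("lin", L = 0, M = c(15, 0.2), S = 0.1,
                        ages = seq(2, 18, by = 0.5))
  for (a in c(2.1, 7.77, 12.25, 17.9))
    expect_equal(lms_at(lin, "female", a)$M, 15 + 0.2 * a, tolerance = 1e-12)
})

test_that("reference CSV round-trips and parse errors name the row", {
  tab <- make_reference("rt", L = c(-1, 0.01), M = c(15, 0.2),
                        S = c(0.08, 0.002), ages = seq(2, 10, by = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_csv(tab, path)
  back <- read_reference_csv(path, name = "rt")
  expect_equal(back$data, tab$data, tolerance = 1e-12)

  two_row <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,age,L,M,S", "both,2,1,16,0.1", "both,10,1,19,0.12"),
             two_row)
  small <- read_reference_csv(two_row)
  expect_equal(nrow(small$data), 4)  # 'both' duplicated into each sex
  expect_equal(age_span(small, "male"), c(2, 10))
  expect_false(small$single_sex)

  unsorted <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,age,L,M,S", "male,5,1,16,0.1", "male,4,1,15,0.1"),
             unsorted)
  expect_error(read_reference_csv(unsorted), "row 2")

  missing_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,age,L,M", "male,5,1,16"), missing_col)
  expect_error(read_reference_csv(missing_col), "missing column")

  bad_cell <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,age,L,M,S", "male,5,1,sixteen,0.1"), bad_cell)
  expect_error(read_reference_csv(bad_cell), "non-numeric")
})
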
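test_that("sphere intensity has the exact forward limit and first zero", {
  expect_equal(sphere_intensity(50, 1000, 0), 1000)
  # first root of tan(x) = x at x = 4.4934095
  expect_lt(sphere_intensity(50, 1000, 4.4934095 / 50), 1e-6)
  expect_error(sphere_intensity(-1, 1, 0.1), "positive")
  expect_error(sphere_intensity(50, 1, c(0.2, 0.1)), "increasing")
})

test_that("sphere p(r) has the analytic shape and second-moment Rg", {
  R <- 50
  r <- seq(0, 2 * R, length.out = 2001)
  p <- sphere_p_of_r(R, r)
  expect_equal(p[1], 0)
  expect_equal(p[length(p)], 0, tolerance = 1e-12)
  expect_true(all(p >= 0))
  amax <- which.max(p)
  expect_gt(r[amax], 0)
  expect_lt(r[amax], 2 * R)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_gt(trapz(r, p), 0)
  # numerical second-moment Rg equals R*sqrt(3/5) within 0.1%
  rg_num <- sqrt(trapz(r, r^2 * p) / (2 * trapz(r, p)))
  expect_lt(abs(rg_num - R * sqrt(3 / 5)) / (R * sqrt(3 / 5)), 0.001)
  expect_error(sphere_p_of_r(R, c(0, 2 * R + 1)), "beyond")
})

test_that("Guinier analysis recovers Rg from ideal and noisy curves", {
  # exact on a pure Gaussian curve
  s <- seq(0.005, 0.1, length.out = 80)
  rg_true <- 20
  gauss <- saxs_curve(s, 50 * exp(-rg_true^2 * s^2 / 3))
  g <- guinier_rg(gauss)
  expect_equal(g$rg, rg_true, tolerance = 1e-8)
  expect_equal(g$i0, 50, tolerance = 1e-8)

  # within 1% on the noise-free sphere curve, R = 50
  tr <- sphere_truth()
  s2 <- seq(tr$s_min, tr$s_max, length.out = tr$n_points)
  ideal <- saxs_curve(s2, sphere_intensity(tr$R, tr$I0, s2))
  g2 <- guinier_rg(ideal)
  expect_lt(abs(g2$rg - 38.73) / 38.73, 0.01)

  # within 3% with 1% noise at a fixed seed
  noisy <- sascifr:::with_seed(7, {
    I <- sphere_intensity(tr$R, tr$I0, s2)
    saxs_curve(s2, I + rnorm(length(s2), 0, 0.01 * I))
  })
  expect_lt(abs(guinier_rg(noisy)$rg - tr$rg) / tr$rg, 0.03)

  expect_error(guinier_rg(saxs_curve(c(0.1, 0.2, 0.3), c(1, 2, 3))),
               "non-negative")
  # broom-style accessors
  td <- tidy(g)
  expect_equal(td$term, c("I0", "Rg"))
  expect_true(all(td$std.error >= 0))
  expect_equal(glance(g2)$rg, g2$rg)
})

test_that("generated file sets honour the format contracts", {
  dir <- withr::local_tempdir()
  tr <- sphere_truth(n_points = 50, n_r = 21, n_beads = 10)
  paths <- generate_entry(tr, dir)
  ncols <- function(path) {
    lines <- readLines(path)
    ar <- vapply(lines, sascifr:::numeric_arity, integer(1), USE.NAMES = FALSE)
    unique(ar[ar > 0])
  }
  expect_equal(ncols(paths$dat), 3)
  expect_equal(ncols(paths$fit), 3)
  expect_setequal(ncols(paths$out), c(2, 3, 5))  # extrapolated, p(r), fit rows
  out_lines <- readLines(paths$out)
  ar <- vapply(out_lines, sascifr:::numeric_arity, integer(1), USE.NAMES = FALSE)
  expect_equal(sum(ar == 5), tr$n_points)
  expect_equal(sum(ar == 3), tr$n_r)
})

test_that("the generated fit is chi-square consistent and beads stay in the sphere", {
  dir <- withr::local_tempdir()
  # N = 200 points, sigma-consistent noise, fixed seed
  tr <- sphere_truth(n_points = 200)
  paths <- generate_entry(tr, dir)
  fit <- read_fitfile(paths$fit)
  expect_lt(abs(attr(fit, "chi2") - 1), 0.2)
  # recomputing from the written columns and the curve errors agrees
  curve <- read_dat(paths$dat)
  chi2 <- reduced_chi2(fit$Iexp, fit$Ifit, curve$err)
  expect_equal(chi2, attr(fit, "chi2"), tolerance = 1e-4)

  beads <- read_pdb(paths$pdb)
  expect_true(all(sqrt(beads$x^2 + beads$y^2 + beads$z^2) <= tr$R + 1e-9))
  # model extent never exceeds Dmax plus two bead radii
  d <- as.matrix(dist(cbind(beads$x, beads$y, beads$z)))
  expect_lte(max(d), tr$dmax + 2 * tr$bead_radius)
})

test_that("generation is deterministic: same seed, byte-identical files", {
  tr <- sphere_truth(n_points = 40, n_r = 11, n_beads = 8, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- generate_entry(tr, d1); p2 <- generate_entry(tr, d2)
  for (k in c("dat", "out", "pdb", "fit", "config", "truth")) {
    expect_identical(readLines(p1[[k]][1]), readLines(p2[[k]][1]))
  }
  p3 <- generate_entry(sphere_truth(n_points = 40, n_r = 11, n_beads = 8,
                                    seed = 100), withr::local_tempdir())
  expect_false(identical(readLines(p1$dat), readLines(p3$dat)))
})

test_that("ground truths agree across routes and pass validation after collect", {
  tr <- sphere_truth()
  s <- seq(tr$s_min, tr$s_max, length.out = tr$n_points)
  rg_guinier <- guinier_rg(saxs_curve(s, sphere_intensity(tr$R, tr$I0, s)))$rg
  r <- seq(0, tr$dmax, length.out = 501)
  p <- sphere_p_of_r(tr$R, r)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  rg_pr <- sqrt(trapz(r, r^2 * p) / (2 * trapz(r, p)))
  expect_lt(abs(rg_guinier - tr$rg) / tr$rg, 0.01)
  expect_lt(abs(rg_pr - tr$rg) / tr$rg, 0.01)

  dir <- withr::local_tempdir()
  paths <- generate_entry(sphere_truth(n_points = 40, n_r = 21, n_beads = 8),
                          dir)
  f <- sascif_collect(paths$dat, out = paths$out, pdb = paths$pdb,
                      fit = paths$fit, config = paths$config)
  expect_equal(nrow(sascif_validate(f)), 0)
})

test_that("autoplot methods build plots for every result type", {
  tr <- sphere_truth(n_points = 30, n_r = 11, n_beads = 5)
  parts <- sascifr:::synthetic_entry_objects(tr)
  expect_s3_class(ggplot2::autoplot(parts$curve), "ggplot")
  expect_s3_class(ggplot2::autoplot(parts$dist), "ggplot")
  expect_s3_class(ggplot2::autoplot(parts$models[[1]]$fit), "ggplot")
  expect_s3_class(ggplot2::autoplot(guinier_rg(parts$curve)), "ggplot")
})
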
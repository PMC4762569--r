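test_that("dat2cif writes the intensity loop and routes metadata", {
  curve <- tiny_curve(metadata = c(sample_description = "lysozyme",
                                   Concentration = "4.0"))
  f <- dat2cif(curve)
  expect_length(cif_get_column(f, "MAIN", "sas_scan_intensity", "intensity"), 3)
  expect_equal(cif_get_column(f, "MAIN", "sas_sample", "name"), "lysozyme")
  expect_equal(cif_get_column(f, "MAIN", "sas_sample", "specimen_concentration"),
               "4.0")
  # s-range items equal the grid extremes
  expect_equal(as.numeric(cif_get_column(f, "MAIN", "sas_scan",
                                         "momentum_transfer_min")), 0.01)
  expect_equal(as.numeric(cif_get_column(f, "MAIN", "sas_scan",
                                         "momentum_transfer_max")), 0.03)
  expect_equal(cif_get_column(f, "MAIN", "sas_scan", "unit"), "1/angstrom")
})

test_that("overwrite policy controls conflicts; replace is idempotent", {
  curve <- tiny_curve()
  f <- dat2cif(curve)
  expect_error(dat2cif(curve, f, overwrite = "error"), "already holds")
  f2 <- dat2cif(curve, f, overwrite = "replace")
  expect_identical(cif_write(f2), cif_write(f))
  # insert tools never touch other blocks
  tr <- sphere_truth(n_points = 20, n_r = 11, n_beads = 5)
  full <- sascif_assemble(synthetic_entry(tr))
  before <- cif_write(full)
  after <- dat2cif(tiny_curve(), full)
  mod_block <- which(tolower(cif_blocks(after)) == "model")
  expect_identical(after$blocks[[mod_block]],
                   cif_parse(before)$blocks[[mod_block]])
})

test_that("cif2dat recovers curves per MAIN block, treating placeholder errors as absent", {
  curve <- tiny_curve()
  back <- cif2dat(dat2cif(curve))
  expect_length(back, 1)
  expect_sigdigits(back[[1]]$s, curve$s)
  expect_sigdigits(back[[1]]$I, curve$I)
  expect_sigdigits(back[[1]]$err, curve$err)
  expect_equal(attr(back[[1]], "metadata"), attr(curve, "metadata"))

  two <- sascif_assemble(list(sas_entry(tiny_curve()), sas_entry(tiny_curve())))
  expect_length(cif2dat(two), 2)

  f <- cif_set_category(cif_new(), "MAIN", "sas_scan_intensity", list(
    id = c("1", "2"), momentum_transfer = c("0.1", "0.2"),
    intensity = c("1", "2"), error = c(NA, NA)), loop = TRUE)
  expect_false("err" %in% names(cif2dat(f)[[1]]))

  expect_warning(out <- cif2dat(cif_new()), "no intensity loop")
  expect_length(out, 0)
})

test_that("out2cif stores the distribution in three categories", {
  tr <- sphere_truth(n_points = 30, n_r = 21)
  parts <- sascifr:::synthetic_entry_objects(tr)
  f <- out2cif(parts$dist, dat2cif(parts$curve))
  expect_true(all(c("sas_p_of_r", "sas_p_of_r_extrapolated_intensity",
                    "sas_p_of_r_details") %in% cif_categories(f, "MAIN")))
  expect_length(cif_get_column(f, "MAIN", "sas_p_of_r", "r"), 21)
  expect_sigdigits(as.numeric(cif_get_column(f, "MAIN", "sas_p_of_r_details",
                                             "dmax")), tr$dmax)
})

test_that("cif2out reconstructs the fit on the experimental grid", {
  tr <- sphere_truth(n_points = 50, n_r = 21)
  parts <- sascifr:::synthetic_entry_objects(tr)
  f <- out2cif(parts$dist, dat2cif(parts$curve))
  d <- cif2out(f)
  # p(r) table identical
  expect_sigdigits(d$pr$p, parts$dist$pr$p)
  # experimental part of the reciprocal grid equals the curve grid
  exp_rows <- !is.na(d$recip$Iexp)
  expect_sigdigits(d$recip$s[exp_rows], parts$curve$s)
  expect_sigdigits(d$recip$Iexp[exp_rows], parts$curve$I)
  expect_error(cif2out(dat2cif(tiny_curve())), "sas_p_of_r")
})

test_that("a coarsely stored regularized fit is re-binned onto every experimental s", {
  # low-angle scan: relative error is well defined only where the form
  # factor is bounded away from its zeros (first minimum at s = 4.493/R)
  tr <- sphere_truth(n_points = 60, n_r = 21, s_max = 0.06)
  parts <- sascifr:::synthetic_entry_objects(tr)
  curve <- parts$curve
  # store the regularized fit on a 2x coarser grid
  coarse_ix <- seq(1, nrow(curve), by = 2)
  s_c <- curve$s[coarse_ix]
  rc <- tibble::tibble(s = s_c,
                       Iexp = curve$I[coarse_ix], err = curve$err[coarse_ix],
                       Ireg = sphere_intensity(tr$R, tr$I0, s_c),
                       Iext = sphere_intensity(tr$R, tr$I0, s_c))
  dist_c <- saxs_pofr(parts$dist$pr, rc, tr$rg, tr$I0, tr$dmax)
  f <- out2cif(dist_c, dat2cif(curve))
  d <- cif2out(f)
  hi <- max(s_c) * (1 + 1e-6)   # stored values carry 7 significant digits
  inside <- d$recip$s >= s_c[1] & d$recip$s <= hi & !is.na(d$recip$Iexp)
  expect_sigdigits(d$recip$s[inside], curve$s[curve$s <= hi])
  expect_true(all(!is.na(d$recip$Ireg[inside])))
  # re-binned values track the analytic curve within 0.5%
  rel <- abs(d$recip$Ireg[inside] -
               sphere_intensity(tr$R, tr$I0, d$recip$s[inside])) /
    sphere_intensity(tr$R, tr$I0, d$recip$s[inside])
  expect_lt(max(rel), 0.005)
})

test_that("rebin_to_grid is exact on affine data and the identity on equal grids", {
  s <- seq(0, 1, by = 0.1)
  I <- 3 + 2 * s
  expect_identical(rebin_to_grid(s, I, s), I)
  dst <- c(0.05, 0.33, 0.71)
  expect_equal(rebin_to_grid(s, I, dst), 3 + 2 * dst, tolerance = 1e-12)
  # outside the source range is absent, not extrapolated
  expect_true(is.na(rebin_to_grid(s, I, 1.5)))
  expect_error(rebin_to_grid(1, 1, s), "at least 2")
  expect_error(rebin_to_grid(c(1, 1), c(1, 2), s), "increasing")
})

test_that("models round-trip through MODEL blocks and separate PDB files", {
  tr <- sphere_truth(n_beads = 6)
  e <- synthetic_entry(tr, n_models = 2)
  f <- sascif_assemble(e)
  texts <- cif2pdb(f)
  expect_length(texts, 2)

  dir <- withr::local_tempdir()
  paths <- names(cif2pdb(f, out_dir = dir))
  expect_length(paths, 2)
  expect_true(all(file.exists(paths)))

  m1 <- read_pdb(paths[1])
  expect_equal(m1$x, e$models[[1]]$model$x, tolerance = 1e-9)

  # one-atom model round trip via pdb2cif
  one <- saxs_model(tibble::tibble(
    record = "ATOM", serial = 1L, name = "CA", resname = "ALA", chain = "A",
    resid = 1L, x = 1, y = 2, z = 3, occ = 1, b = 0, element = "C"))
  g <- pdb2cif(one, cif_new())
  expect_equal(cif_blocks(g), "MODEL")
  back <- read_pdb(cif2pdb(g)[[1]])
  expect_equal(c(back$x, back$y, back$z), c(1, 2, 3), tolerance = 1e-9)

  # bead radius survives the round trip
  expect_equal(attr(sascifr:::extract_model(f, "MODEL"), "bead_radius"),
               tr$bead_radius)
})

test_that("fits land in FIT blocks without errors, which stay with the curve", {
  tr <- sphere_truth(n_points = 40, n_r = 11, n_beads = 5)
  parts <- sascifr:::synthetic_entry_objects(tr)
  fir <- saxs_fit(parts$curve$s, parts$curve$I, parts$models[[1]]$fit$Ifit,
                  err = parts$curve$err, chi2 = 1.0)
  f <- dat2cif(parts$curve)
  f <- pdb2cif(parts$models[[1]]$model, f)
  f <- fit2cif(fir, f, model_id = 1)
  # no error column stored in the FIT block
  expect_null(cif_get_column(f, "FIT", "sas_model_fitting", "error"))
  # .fir reconstruction pulls the errors back from sas_scan_intensity
  fir_back <- read_fitfile(cif2fit(f, dialect = "fir")[[1]], "fir")
  expect_sigdigits(fir_back$err, parts$curve$err)

  fit_back <- read_fitfile(cif2fit(f)[[1]], "fit")
  expect_equal(attr(fit_back, "chi2"), 1.0)
  expect_false("err" %in% names(fit_back))

  # a fit referencing an unknown model id is an error
  expect_error(fit2cif(saxs_fit(1:2, 1:2, 1:2), f, model_id = 9),
               "unknown model id")
  # no link at all: warning, link left unset
  expect_warning(g <- fit2cif(saxs_fit(1:2, 1:2, 1:2), dat2cif(tiny_curve())),
                 "no model link")
  expect_true(is.na(cif_get_column(g, "FIT", "sas_model_fitting_details",
                                   "model_id")))

  e2 <- synthetic_entry(tr, n_models = 2)
  expect_length(cif2fit(sascif_assemble(e2)), 2)
})

test_that("cif2sub flattens every populated scalar item and nothing else", {
  tr <- sphere_truth(n_points = 20, n_r = 11, n_beads = 5)
  f <- sascif_assemble(synthetic_entry(tr))
  sub <- cif2sub(f)
  expect_equal(unname(sub["sample_name"]), "synthetic homogeneous sphere")
  expect_equal(unname(sub["buffer_ph"]), "7.5")
  expect_false(any(grepl("citation", names(sub))))

  # line count = number of populated scalar non-id items across all blocks
  n_scalar <- 0
  for (b in f$blocks) {
    for (cc in b$categories) {
      if (cc$loop) next
      ok <- cc$items != "id" &
        vapply(cc$kinds, function(k) k[1] == "t", logical(1))
      n_scalar <- n_scalar + sum(ok)
    }
  }
  expect_length(sub, n_scalar)

  path <- withr::local_tempfile(fileext = ".txt")
  cif2sub(f, path = path)
  expect_length(readLines(path), n_scalar)
})

test_that("cif2all extracts everything and keeps going on per-component failures", {
  tr <- sphere_truth(n_points = 20, n_r = 11, n_beads = 5)
  f <- sascif_assemble(synthetic_entry(tr))
  dir <- file.path(withr::local_tempdir(), "nested", "out")
  man <- cif2all(f, out_dir = dir)   # out_dir created if missing
  expect_true(dir.exists(dir))
  expect_gte(sum(man$status == "written"), 5)
  expect_setequal(man$kind, c("dat", "out", "pdb", "fit", "sub"))

  lean <- cif2all(dat2cif(tiny_curve()), out_dir = withr::local_tempdir())
  expect_setequal(lean$kind[lean$status == "written"], c("dat", "sub"))
})

test_that("collect builds the full entry from a legacy file set", {
  tr <- sphere_truth(n_points = 40, n_r = 21, n_beads = 6)
  dir <- withr::local_tempdir()
  paths <- generate_entry(tr, dir)
  f <- sascif_collect(paths$dat, out = paths$out, pdb = paths$pdb,
                      fit = paths$fit, config = paths$config)
  expect_equal(cif_blocks(f), c("MAIN", "MODEL", "FIT"))
  expect_equal(cif_get_column(f, "MAIN", "sas_beam", "name"),
               "synthetic beamline")
  expect_equal(cif_get_column(f, "MODEL", "sas_model", "type"), "ab-initio")
  expect_equal(nrow(sascif_validate(f)), 0)

  expect_error(sascif_collect(file.path(dir, "missing.dat")), "mandatory")

  # config-only beam metadata lands in sas_beam
  g <- sascif_collect(paths$dat, config = c(beam_name = "P12"))
  expect_equal(cif_get_column(g, "MAIN", "sas_beam", "name"), "P12")
})

test_that("collect then cif2all reproduces the input tables", {
  tr <- sphere_truth(n_points = 40, n_r = 21, n_beads = 6)
  dir <- withr::local_tempdir()
  paths <- generate_entry(tr, dir)
  f <- sascif_collect(paths$dat, out = paths$out, pdb = paths$pdb,
                      fit = paths$fit, config = paths$config)
  out_dir <- file.path(dir, "extracted")
  man <- cif2all(f, out_dir = out_dir)
  get1 <- function(kind) man$path[man$kind == kind & man$status == "written"]

  c0 <- read_dat(paths$dat); c1 <- read_dat(get1("dat"))
  expect_sigdigits(c1$s, c0$s); expect_sigdigits(c1$I, c0$I)
  expect_sigdigits(c1$err, c0$err)
  expect_equal(attr(c1, "metadata"), attr(c0, "metadata"))

  d0 <- read_out(paths$out); d1 <- read_out(get1("out"))
  expect_sigdigits(d1$pr$p, d0$pr$p)
  expect_sigdigits(d1$dmax, d0$dmax)

  m0 <- read_pdb(paths$pdb)
  m1 <- read_pdb(Sys.glob(file.path(out_dir, "*model*.pdb")))
  expect_equal(m1$x, m0$x, tolerance = 1e-9)

  f0 <- read_fitfile(paths$fit)
  f1 <- read_fitfile(Sys.glob(file.path(out_dir, "*fit*.fit")))
  expect_sigdigits(f1$Ifit, f0$Ifit)
  expect_sigdigits(attr(f1, "chi2"), attr(f0, "chi2"))
})
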
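test_that("read_dat parses metadata headers and 2- or 3-column data", {
  c1 <- read_dat("Sample: lysozyme\n0.01 100.0 1.0\n0.02 99.0 1.1")
  expect_equal(nrow(c1), 2)
  expect_equal(attr(c1, "metadata")[["Sample"]], "lysozyme")
  expect_equal(c1$err, c(1.0, 1.1))

  c2 <- read_dat("0.01 100\n0.02 99")
  expect_false("err" %in% names(c2))

  expect_error(read_dat("just text\nno numbers"), "numeric")
  expect_error(read_dat("0.02 100 1\n0.01 99 1"), "increasing")
  expect_warning(read_dat("0.01 1 1\n0.02 2 1\ntrailing junk"), "trailing")
})

test_that("write_dat keeps the three-column contract and round-trips", {
  curve <- tiny_curve()
  txt <- write_dat(curve)
  data_rows <- grep("^[ -]?[0-9]", strsplit(txt, "\n")[[1]], value = TRUE)
  expect_true(all(lengths(strsplit(trimws(data_rows), "[ \t]+")) == 3))

  back <- read_dat(txt)
  expect_sigdigits(back$s, curve$s)
  expect_sigdigits(back$I, curve$I)
  expect_sigdigits(back$err, curve$err)
  expect_equal(attr(back, "metadata"), attr(curve, "metadata"))

  # absent errors: zeros in column 3 by default, two columns on request
  noerr <- saxs_curve(c(0.1, 0.2), c(5, 4))
  expect_match(write_dat(noerr), "0.000000e\\+00")
  expect_equal(max(lengths(strsplit(
    trimws(strsplit(write_dat(noerr, three_columns = FALSE), "\n")[[1]]),
    " +"))), 2)

  # no metadata: file starts directly with numbers; 1-point curve: one row
  one <- saxs_curve(0.1, 5, err = 0.1)
  lines <- strsplit(write_dat(one), "\n")[[1]]
  expect_length(lines, 1)
  expect_match(lines[1], "^[0-9]")
})

test_that("curve invariants are enforced", {
  expect_error(saxs_curve(c(0.2, 0.1), c(1, 2)), "increasing")
  expect_error(saxs_curve(c(-0.1, 0.1), c(1, 2)), "non-negative")
  expect_error(saxs_curve(c(0.1, 0.2), c(1, 2), err = 1), "length")
})

test_that(".out files round-trip with sections located by shape", {
  tr <- sphere_truth(n_points = 40, n_r = 21)
  parts <- sascifr:::synthetic_entry_objects(tr)
  d <- parts$dist
  txt <- write_out(d)
  back <- read_out(txt)

  expect_equal(back$pr$r[1], 0)
  expect_sigdigits(tail(back$pr$r, 1), d$dmax)
  expect_sigdigits(back$dmax, d$dmax)
  expect_sigdigits(back$rg, d$rg)
  expect_sigdigits(back$i0, d$i0)
  expect_sigdigits(back$pr$p, d$pr$p)
  # reciprocal rows = experimental + extrapolated
  n_ext <- sum(is.na(d$recip$Iexp))
  expect_equal(nrow(back$recip), tr$n_points + n_ext)
  expect_equal(sum(is.na(back$recip$Iexp)), n_ext)
  expect_sigdigits(back$recip$Iext, d$recip$Iext)
  expect_sigdigits(back$recip$Ireg[!is.na(back$recip$Ireg)],
                   d$recip$Ireg[!is.na(d$recip$Ireg)])

  expect_error(read_out("no tables here"), "p\\(r\\)")
})

test_that("distance-distribution invariants are enforced", {
  pr <- tibble::tibble(r = c(0, 1, 2), p = c(0, 1, 0), perr = 0.1)
  rc <- tibble::tibble(s = c(0.1, 0.2), Iexp = 1, err = 0.1, Ireg = 1, Iext = 1)
  expect_s3_class(saxs_pofr(pr, rc, 1, 1, 2), "saxs_pofr")
  bad_pr <- tibble::tibble(r = c(1, 2), p = c(1, 0), perr = 0.1)
  expect_error(saxs_pofr(bad_pr, rc, 1, 1, 2), "r = 0")
  bad_rc <- rc[c(2, 1), ]
  expect_error(saxs_pofr(pr, bad_rc, 1, 1, 2), "increasing")
})

test_that("fit files honour the 3/4-column dialect contract", {
  fir_txt <- "Chi^2: 1.23\n0.01 100 1.0 99\n0.02 98 1.1 97.5"
  fir <- read_fitfile(fir_txt, dialect = "fir")
  expect_true("err" %in% names(fir))
  expect_equal(attr(fir, "chi2"), 1.23)

  fit_txt <- "0.01 100 99\n0.02 98 97.5"
  fit <- read_fitfile(fit_txt, dialect = "fit")
  expect_false("err" %in% names(fit))
  expect_true(is.na(attr(fit, "chi2")))

  # auto-dialect from column count
  expect_true("err" %in% names(read_fitfile(fir_txt)))
  expect_false("err" %in% names(read_fitfile(fit_txt)))
  # explicit dialect inconsistent with the data is an error
  expect_error(read_fitfile(fit_txt, dialect = "fir"), "inconsistent")
  expect_error(read_fitfile(fir_txt, dialect = "fit"), "inconsistent")

  # alternative chi2 spellings and p value
  expect_equal(attr(read_fitfile("chi2 = 2.5\n1 2 3\n2 3 4"), "chi2"), 2.5)
  expect_equal(attr(read_fitfile("Chi-square: 0.9 p-value: 0.04\n1 2 3\n2 3 4"),
                    "cormap_p"), 0.04)
})

test_that("write_fitfile is the inverse of read_fitfile", {
  f <- saxs_fit(c(0.01, 0.02, 0.03), c(10, 9, 8), c(9.9, 9.1, 8.05),
                err = c(0.1, 0.1, 0.1), chi2 = 1.0, cormap_p = 0.5)
  for (dialect in c("fit", "fir")) {
    txt <- write_fitfile(f, dialect)
    ncols <- if (dialect == "fir") 4 else 3
    rows <- grep("^[0-9 .e+-]+$", strsplit(txt, "\n")[[1]], value = TRUE)
    expect_true(all(lengths(strsplit(trimws(rows), " +")) == ncols))
    back <- read_fitfile(txt, dialect)
    expect_sigdigits(back$s, f$s)
    expect_sigdigits(back$Ifit, f$Ifit)
    expect_equal(attr(back, "chi2"), 1.0)
    expect_equal(attr(back, "cormap_p"), 0.5)
  }
  # chi2 header emitted iff set
  f2 <- saxs_fit(c(1, 2), c(1, 1), c(1, 1))
  expect_false(grepl("Chi", write_fitfile(f2)))
  expect_error(write_fitfile(f2, "fir"), "error column")
})

test_that("PDB records parse at fixed columns and round-trip to 3 decimals", {
  line <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 20.00           C"
  m <- read_pdb(c(line, "END"))
  expect_equal(nrow(m), 1)
  expect_equal(c(m$x, m$y, m$z), c(1, 2, 3))
  expect_equal(m$resname, "ALA")
  expect_equal(m$element, "C")

  back <- read_pdb(write_pdb(m))
  expect_equal(back$x, m$x, tolerance = 1e-9)
  expect_equal(back$serial, m$serial)

  expect_error(read_pdb("ATOM      1  CA  ALA A   1       xxx"), "line 1")
  expect_error(read_pdb("REMARK only"), "no ATOM")
})

test_that("dummy-atom bead models round-trip atom count exactly", {
  tr <- sphere_truth(n_beads = 37)
  beads <- sascifr:::with_seed(1, sascifr:::sphere_beads(tr))
  m <- saxs_model(beads, model_type = "ab-initio", bead_radius = tr$bead_radius)
  back <- read_pdb(write_pdb(m))
  expect_equal(nrow(back), 37)
  expect_true(all(back$resname == "DUM"))
  expect_equal(back$x, m$x, tolerance = 1e-9)
})

test_that("our PDB writer agrees with an independent reader", {
  tr <- sphere_truth(n_beads = 10)
  m <- saxs_model(sascifr:::with_seed(7, sascifr:::sphere_beads(tr)),
                  model_type = "ab-initio")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  ref <- bio3d::read.pdb(path)
  expect_equal(unname(ref$atom$x), m$x, tolerance = 1e-9)
  expect_equal(unname(ref$atom$y), m$y, tolerance = 1e-9)
  expect_equal(unname(ref$atom$z), m$z, tolerance = 1e-9)
  expect_equal(unname(ref$atom$resid), m$resname)
})
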
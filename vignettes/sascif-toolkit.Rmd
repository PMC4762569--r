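---
title: "The sasCIF toolkit: model, converters and synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sasCIF toolkit: model, converters and synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sascifr)
```

## The problem this package addresses

A small-angle X-ray or neutron scattering (SAXS/SANS) experiment on a
macromolecule in solution produces a one-dimensional intensity curve
$I(s)$ versus the momentum transfer $s = 4\pi\sin\theta/\lambda$. Routine
analysis derives the radius of gyration $R_g$ and forward scattering
$I(0)$ (Guinier analysis), the pair-distance distribution $p(r)$ with its
maximum dimension $D_{max}$ (indirect Fourier transform), and spatial
models — ab initio bead models or atomic structures — whose computed
scattering is fitted to the data with a reduced $\chi^2$ or a
correlation-map $p$ value. Each step traditionally leaves its own ASCII
file behind: three-column `.dat` curves, indirect-transform `.out` files,
three-column `.fit` / four-column `.fir` model fits, and PDB coordinate
files.

sasCIF is a CIF/STAR dialect that archives all of this — data, transforms,
models, fits and experiment metadata — in one self-describing text file,
organised in MAIN / MODEL / FIT data blocks. This package implements the
format end to end in R: an order-preserving CIF parser and writer, the
sasCIF category model with validation, bidirectional converters for the
legacy formats, an entry collector for pipeline use, and a synthetic-data
generator so every conversion can be verified against closed-form ground
truth.

## The CIF layer and its numerical choices

The in-memory model (`cif_file`) is an ordered list of data blocks, each
an ordered set of categories holding ordered items. CIF itself does not
require any ordering, but predictable output matters for human readers and
for diff-based archives, so order is preserved exactly through
`cif_parse()` / `cif_write()`, and a write–parse–write cycle is
byte-stable (this is a tested invariant).

Decisions a reader of CIF files must make, and how this package makes
them:

* **Placeholders.** `?` (missing) and `.` (inapplicable) are tracked as
  value *kinds*, distinct from the literal text `"?"` or `"."`; a text
  value that looks like a placeholder is always written quoted so it
  cannot be re-read as one.
* **Numbers are text.** The core stores every value as its source text
  and never reformats numbers it did not create, so files round-trip
  losslessly at whatever precision they were written with. Converters
  that *create* values write `%.6e` (7 significant digits) for tables and
  `%8.3f` for PDB coordinates — instrument precision with fixed-width
  safety.
* **Quoting.** Single quotes are preferred, double quotes are the
  fallback when the value contains a single quote followed by whitespace,
  and semicolon text blocks are used only for values containing newlines
  (or quotes in both styles). Values that could be misread as directives
  (`data_...`, `loop_`) or comments (`#...`) are quoted.
* **Names.** Block, category and item names compare case-insensitively;
  category and item names are stored and emitted lowercase.
* **Scope.** CIF 1.1 data-file subset only: no save frames, no nested
  loops, no CIF2 bracket values — sasCIF data files use none of these.
  Loops must keep all items in one category, and a loop whose value count
  is not an exact multiple of its item count is a syntax error.

## The sasCIF model

The category vocabulary lives in a plain-text registry
(`inst/extdata/sascif_categories.tsv`, see `sascif_registry()`): item
names, required flags, value domains (free text, number, enumerations
such as the momentum-transfer unit `1/angstrom` / `1/nm`), key items and
parent–child links. Several item names that are not spelled out in any
printed description of the format are local choices and are flagged
`origin = local` in the registry, so they can be renamed centrally if a
canonical spelling emerges; the registry asset can evolve without code
changes.

Block structure: every scalar-per-measurement category lives in the MAIN
block; each spatial model gets its own MODEL block (`sas_model` +
`atom_site` in PDBx naming) and each fit its own FIT block
(`sas_model_fitting_details` + `sas_model_fitting`), because a category
may appear only once per block and a file may hold several models and
fits. Integer ids link a FIT to its MODEL. Labels are `MAIN`, `MODEL`,
`FIT` for the first of each family, then `MODEL2`, `FIT2`, ...; a
concentration or contrast series is a list of entries mapping to `MAIN`,
`MAIN2`, .... Model ids are kept globally unique across the file, which
makes dangling-link detection (`sascif_split()` errors, `sascif_validate()`
reports) unambiguous.

`sascif_validate()` never throws: findings are rows (`error` or
`warning`) in a report tibble. Unknown categories and items are warnings,
not errors — locally extended files remain readable and their content is
preserved verbatim on round trip.

## Converters

* `dat2cif()` / `cif2dat()`: the intensity loop plus metadata routing. A
  fixed map links `.dat` header keys to categories (sample name and
  concentration to `sas_sample`; title, unit, temperatures and frame
  count to `sas_scan`); unrecognized header keys are preserved as extra
  `sas_scan` items (flagged by validation, kept on round trip). The
  momentum-transfer range items are always recomputed from the grid
  extremes.
* `out2cif()` / `cif2out()`: the three p(r) categories. On extraction the
  regularized intensities are translated back to the angular increments
  of the original curve: the stored grid may be coarser (indirect
  transform programs re-bin dense data for speed), so `cif2out()`
  re-bins the stored $I_{reg}$ onto the experimental grid held in
  `sas_scan_intensity`. Re-binning (`rebin_to_grid()`) is linear
  interpolation — exact for locally linear data, the identity on an
  unchanged grid, and easy to verify against an independent oracle; the
  target points outside the stored range are absent (`NA`), never
  extrapolated. Rows of the stored grid below the experimental minimum
  (the extrapolation towards $s = 0$) have no experimental counterpart
  and stay on their stored grid.
* `pdb2cif()` / `cif2pdb()`: fixed-column PDB parsing and the standard
  PDB-to-PDBx field correspondence for `atom_site`; one PDB file per
  MODEL block on extraction.
* `fit2cif()` / `cif2fit()`: `.fit` (3 columns) and `.fir` (4 columns)
  dialects. Experimental errors are deliberately *not* stored in FIT
  blocks — they belong with the original data in `sas_scan_intensity` —
  so `cif2fit()` emits `.fit` by default and can reconstruct `.fir` only
  when the fit grid matches a stored curve that has errors. The reduced
  $\chi^2$ and correlation-map $p$ value live in
  `sas_model_fitting_details` and are emitted in the fit-file header.
  Model-versus-data scaling is assumed already applied upstream;
  converters never rescale.
* `cif2sub()` flattens every populated scalar item (structural `id`
  items excluded) to `name : value` lines such as `sample_name`,
  `buffer_ph`, `result_dmax`; blocks after the first MAIN contribute a
  lower-cased block-label prefix. The same naming in reverse routes the
  metadata config of `sascif_collect()`, so a `cif2sub()` dump is a valid
  collect config.
* `cif2all()` runs every extractor, one output directory, one manifest
  tibble; a failing component is recorded and the others continue.
* Insert tools touch only their target block. The conflict policy is
  explicit: `overwrite = "replace"` makes re-runs idempotent,
  `"error"` raises when the target category already exists.

## The synthetic-data generator

All tests run on entries generated from a homogeneous sphere of radius
$R$, because every derived quantity has a closed form:

$$I(s) = I(0)\,\Big[\frac{3(\sin sR - sR\cos sR)}{(sR)^3}\Big]^2,
\qquad
p(r) \propto r^2\Big(1 - \frac{3r}{4R} + \frac{r^3}{16R^3}\Big)
\;\; (0 \le r \le 2R),$$

with $R_g = R\sqrt{3/5}$ exactly, $D_{max} = 2R$ exactly, and the first
intensity zero at $s = 4.4934/R$ (the first positive root of
$\tan x = x$).

Default conditions (`sphere_truth()`), chosen once as a realistic
benchtop scenario:

* $R = 50$ Å ($R_g = 38.73$ Å, $D_{max} = 100$ Å) — a mid-sized globular
  particle;
* $I(0) = 1000$, arbitrary units;
* curve grid: 1000 points, $s \in [0.005, 0.5]$ Å$^{-1}$ — synchrotron
  beamline-like sampling, dense enough that the Guinier window holds
  $\sim$30 points;
* noise: Gaussian with $\sigma(s) = f\,(I(s) + 0.01\,I(0))$, $f = 1\%$.
  The additive floor keeps $\sigma > 0$ through the form-factor zeros;
  Gaussian rather than Poisson because the intensity units are
  arbitrary. The generated `.fit` pairs the noisy curve with the
  noise-free one, so its reduced
  $\chi^2 = \frac{1}{N-1}\sum\big(\frac{I_{exp}-I_{fit}}{\sigma}\big)^2$
  is $\approx 1$ by construction ($\pm 2\sqrt{2/N}$ statistically);
* $p(r)$ on 101 points in $[0, 2R]$, scaled so $\int p\,dr = I(0)$;
* bead model: 50 dummy atoms (residue `DUM`, chain `A`, unit occupancy,
  bead radius 3 Å) rejection-sampled uniformly inside the sphere —
  the conventions of ab initio bead modelling.

Generation is seeded and deterministic: the same `sphere_truth()` gives a
byte-identical file set, and the caller's RNG stream is left untouched.

### The Guinier window

`guinier_rg()` iterates an unweighted least-squares line on
$(s^2, \ln I)$ to self-consistency of the window $s\,R_g \le$
`s_rg_max`. The familiar 1.3 rule of thumb is calibrated for globular
proteins; for an *ideal sphere* the quartic term of $\ln I(s)$ is
stronger, and at $s R_g \le 1.3$ the fitted $R_g$ comes out high by
almost 2% no matter how dense the grid — which would defeat the
generator's own 1%-consistency contract between the Guinier estimate,
the $p(r)$ second moment and the exact $R_g$. The default window is
therefore 0.8, where the bias stays below 1%:

```{r guinier-bias}
s <- seq(0.005, 0.5, length.out = 1000)
ideal <- saxs_curve(s, sphere_intensity(50, 1000, s))
rg_true <- 50 * sqrt(3 / 5)
for (w in c(0.8, 1.3)) {
  rg <- guinier_rg(ideal, s_rg_max = w)$rg
  cat(sprintf("window %.1f: Rg = %.3f (%+.2f%%)\n",
              w, rg, 100 * (rg - rg_true) / rg_true))
}
```

On noisy curves the estimate scatters: with 1% noise and the default
grid the window holds about 30 points and the standard error of the
fitted $R_g$ is on the order of 1.5%, so a 3% agreement with truth is a
typical, not a guaranteed, outcome of a noise realization.

### Where relative comparisons are well posed

The sphere form factor has zeros ($s = 4.4934/R, \ldots$) where the
intensity vanishes; point-wise *relative* error against the analytic
curve is unbounded there for any interpolation scheme. Accuracy checks
of `rebin_to_grid()` against the analytic intensity are therefore made
on a dense low-angle scan ($s \le 0.08$ Å$^{-1}$ for $R = 50$ Å, i.e.
below the first zero), where the comparison is meaningful; on that
fixture a 2$\times$ coarser source grid re-bins to well within 0.5% of
the analytic values. Exactness on affine intensities is asserted at
machine precision separately.

### What the generator does not emulate

Instrumental smearing, concentration effects and inter-particle
structure factors, Poisson counting statistics, buffer-subtraction
artefacts, and the historical fixed-width layout of real
indirect-transform output (the `.out` reader is tolerant — labelled
header search plus column-count section detection — but byte-level
compatibility with legacy files is a non-goal). Passing tests therefore
demonstrate the correctness of the format layer and converters, not the
robustness of the physics helpers against real-data pathologies.

## Degenerate inputs and tie-breaks

* Monotonicity of $s$ and $r$ is enforced on read; violating inputs are
  rejected (or reported by `sascif_validate()` when already in a file).
* A curve error column that is entirely placeholders extracts as an
  absent `err`; `write_dat()` keeps the three-column contract by writing
  zeros (a flag restores two-column output).
* A fit with no model link is inserted with a warning and an
  inapplicable link; a fit referencing a non-existent model id is an
  error on insert and on split.
* `guinier_rg()` needs at least 3 usable points and a negative slope;
  otherwise it errors rather than returning a complex $R_g$.
* Values unrepresentable in CIF 1.1 (a value containing both a newline
  and a line starting with `;`) raise an error at write time.

## Problem sizes in the checks

The test-suite and the acceptance script run entirely on generated data,
at sizes chosen to exercise every code path while the whole suite stays
in the tens-of-seconds range: curves of 30–1000 points, $p(r)$ tables of
11–101 points, bead models of 5–50 atoms, 10-seed entry round trips and
a 20-file byte-stability corpus.

## Known limitations

* CIF 1.1 data files only — no dictionaries (DDL), no CIF2.
* One curve per entry; series are lists of entries. In a multi-MAIN file
  models and fits attach to the first entry on `sascif_split()`.
* `.fir` reconstruction requires the fit grid to match a stored curve
  exactly (no tolerance-based grid matching).
* The SASBDB database side (SQL export, oligomer-word and citation
  free-text preprocessing) is outside this package's scope; the flat
  metadata config of `sascif_collect()` mirrors what such a pipeline
  would supply.
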
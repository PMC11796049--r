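---
title: "From potentiostat files to FAIR cyclic-voltammetry datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From potentiostat files to FAIR cyclic-voltammetry datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltfair)
```

## The problem

A cyclic voltammetry (CV) experiment sweeps the working-electrode
potential linearly between vertex potentials and records the current.
Every instrument vendor stores the result differently, and the metadata
needed to interpret a voltammogram — scan rate, potential window,
electrodes, electrolyte, reference couple — is split between the
instrument file and the experimentalist's head. `voltfair` implements a
pipeline that makes such measurements findable, interoperable and
re-usable: vendor file → uniform raw model → per-cycle JCAMP-DX +
mapped metadata → checksummed BagIt bag → picked peaks and standardized
descriptors → spreadsheet and archive exports.

This vignette documents the models, algorithms, defaults and numerical
choices behind each stage, and what the package's tests do and do not
demonstrate.

## The simulator: a reversible couple as ground truth

All test inputs are produced by `simulate_cv()`, which models the one
redox system whose behaviour is known in closed form well enough to act
as ground truth: a **reversible (Nernstian) one-electron couple** under
1-D semi-infinite diffusion, with equal diffusion coefficients for both
forms.

The reduced form R (bulk concentration `C_bulk`) is oxidised at the
electrode. With equal diffusivities the total concentration is uniform,
so only R is simulated. At every instant the surface concentration obeys
the Nernst equation,

\[ C_R(0, t) = \frac{C_\mathrm{bulk}}{1 + \exp\!\big(nF(E - E^0)/RT\big)}, \]

and the current follows from the surface gradient,
\( I = n F A D\, \partial C_R/\partial x \rvert_{x=0} \). The diffusion
field is advanced with an explicit forward-time central-space (FTCS)
scheme on a uniform grid spanning \(6\sqrt{D\,t_\mathrm{max}}\) (beyond
which the solution stays at bulk). A capacitive term
\( \pm \nu C_\mathrm{dl} \) and, last, seeded Gaussian current noise are
added. Identical parameters (including the seed) therefore give
byte-identical fixture files.

### Numerical choices

* **Stability.** FTCS requires \( \lambda = D\,\Delta t/\Delta x^2 \le
  0.45 \). Each sampling interval `dt` is divided into `substeps`
  diffusion sub-steps and the spatial step is placed at the stability
  limit, so more sub-steps buy a finer grid. A user-forced grid
  (`n_space`) that violates the bound is rejected with a configuration
  error.
* **Continuous boundary.** Applying the Nernstian surface value as a
  step at each sample creates a Cottrell-like transient whose error in
  the peak positions decays only like \(\sqrt{\Delta t}\) (at 2 mV
  potential steps it broadens the peak separation by >10 mV). The
  surface concentration is therefore ramped linearly across the
  sub-steps of each sample, keeping the boundary continuous.
* **Defaults.** The reference condition is a 1 mM couple with
  \(D = 10^{-5}\,\mathrm{cm^2\,s^{-1}}\) on a 0.1 cm² electrode, scanned
  anodically first over ±0.35 V around \(E^0 = 0\) at 0.1 V/s for
  3 cycles at 298.15 K, sampled every 0.5 mV (`dt = 0.005` s,
  `substeps = 12`). These are ordinary bench conditions for a
  small-molecule redox couple; the window leaves ≈ 320 mV beyond each
  peak. Halving `dt` at the defaults changes the peak currents by less
  than 1 % (grid convergence).
* **Accuracy.** Against an independent semi-analytical solution
  (Grünwald–Letnikov half-derivative of the exact surface-concentration
  history), the converged peak separation of this condition is
  57.5–58 mV; the FTCS grid at the default resolution reproduces
  60–61 mV and centres \(E_{1/2}\) on \(E^0\) to well under 1 mV.

### What the simulator does and does not emulate

It emulates the staircase potential program, diffusion-limited faradaic
response, capacitive offset and white current noise — enough to exercise
every pipeline stage with known ground truth. It does **not** model
electrode kinetics (Butler–Volmer quasi-reversibility), coupled
chemistry (EC mechanisms), uncompensated resistance, or drift; passing
tests therefore show the pipeline is faithful to an ideal reversible
measurement, not that peak picking is robust to every pathology of real
electrochemistry.

### A consequence worth stating: the zero-line ratio of a reversible couple is not 1

"`ipa/ipc ≈ 1` for a chemically reversible couple" refers to peak
currents measured against the *extrapolated forward-branch baseline*.
Measured from the zero-current line — which is what automatic picking on
a bare voltammogram gives — the reverse peak rides on the decaying
diffusional tail of the forward sweep and is systematically small. The
semi-analytical oracle puts the zero-line ratio of the reference
condition at 1.31 on the first cycle, 1.18 on the second and still
≈ 1.09 after six cycles; it approaches 1 only in the many-cycle
steady state. This is exactly the bias the Nicholson switching-current
correction removes: with the current at the switching potential
\(i_{\lambda 0}\) (a user-determined quantity in this workflow),

\[ \frac{i_{pa}}{i_{pc}} = \frac{|i_{rev,0}|}{|i_{fwd,0}|}
   + 0.485\,\frac{|i_{\lambda 0}|}{|i_{fwd,0}|} + 0.086 , \]

which evaluates to 1.00–1.01 for the simulated couple's first cycle.
`compute_descriptors()` exposes both modes — `"direct"` because it is
transparent and reproducible, `"nicholson"` because it is the
scientifically corrected figure — and reports which one produced the
number. The package's tests assert the direct first-cycle ratio only
against the oracle-confirmed value, and the corrected ratio against
unity.

## Sweep segmentation

`segment_sweeps()` partitions a trace into monotone potential sweeps:

* the sign of `diff(E)` defines the local direction; zero differences
  (staircase plateaus) inherit the previous direction;
* a direction change is accepted only when the new direction persists
  for at least `min_run` samples (default 3, i.e. two consecutive
  differences) — single-sample jitter cannot split a sweep;
* every point belongs to exactly one sweep, the vertex sample closing
  the sweep it ends, so concatenating all sweeps reproduces the trace
  exactly (this conservation is asserted, elementwise, in the tests).

Consecutive sweep pairs form cycles (`assemble_cycles()`); an unpaired
trailing sweep becomes a cycle flagged `partial`.

The scan rate is inferred as the **median** of `|ΔE/Δt|` over in-sweep
sample pairs, reported to 3 significant figures. The median, unlike the
mean, is unaffected by vertex samples, dropped points, or a handful of
corrupted timestamps; on noiseless staircase data it is exact.

## Conversion profiles and the metadata scheme

A conversion profile is defined once per device and then applies to all
its files. Matching is identifier-based (regular expressions over the
file name, header `key=value` pairs, or table names); all *required*
rules must hit. When several profiles qualify, the one satisfying the
most rules wins, and remaining ties resolve to the lexicographically
smallest profile id — matching is deterministic, and a file matching no
profile is parked rather than mis-converted.

The target metadata scheme (version 1.0) covers sample and analyte
identity, cell composition, the electrode setup, the potential program,
instrument provenance, and the method ontology term (defaulting to
"cyclic voltammetry (CV)" from CHMO). Each field carries a unit and a
provenance tag: `device` (extracted from the file), `context` (from the
lab's documentation system), `manual` (typed by a person), `analysis`
(derived by the peak analysis), `computed` (derived from the raw data),
or `missing`. Where a file has no mappable headers at all, the essential
fields — scan rate, potential window, cycle count — are computed from
the data, so conversion never fails for lack of metadata; it degrades to
warnings. Validation is report-only and two-tiered: `minimal` (scan rate
and potential window) and `publication` (additionally electrodes,
electrolyte, solvent, reference couple); the split is this package's
stratification of common reporting guidance.

`merge_metadata()` combines the four provenance parts with precedence
**manual > analysis > context > device**: a human correcting a record
must always win, an analysis result beats what the instrument guessed,
and conflicts are logged rather than silently dropped. The merge is
idempotent, and records serialize losslessly to JSON (unknown fields
survive in an extensions section).

## JCAMP-DX representation

Each cycle becomes one JCAMP-DX 5.01 document. CV abscissae are
non-monotonic, so the equal-increment `XYDATA` form does not apply; data
are written as explicit `XYPOINTS` pairs in acquisition order, plain
AFFN numbers at 6 significant digits, `.` decimal, LF line endings. The
fixed formatting makes serialization canonical: parsing and re-writing
an unmodified document is byte-identical, which the tests exploit for
golden comparisons. Scheme metadata is embedded as
`##$<UPPERCASE_FIELD_ID>=` user LDRs (the authoritative record lives in
the bag's JSON); unknown LDRs are preserved verbatim. Peak tables are
appended as separate blocks tagged with their origin (`auto` or
`manual`); the first block — the original data — is never touched, and
a later block replaces an earlier peak table rather than stacking. No
NMR/IR compression schemes (DIFDUP, SQZ) are produced or consumed.

## BagIt bags and the dataset archive

A bag contains `bagit.txt` (version + encoding), `data/` with one
JCAMP-DX file per cycle, `manifest-sha256.txt` and `manifest-sha512.txt`
covering every payload file, and `metadata/metadata.json` with the
merged record. Canonical BagIt has no `metadata/` sibling of `data/`;
this layout follows the workflow the package implements, and the
validator treats `metadata/` as a tag directory (not manifest-covered)
and says so in its report. Validation recomputes every digest, so any
single-byte payload mutation is caught.

The downloadable archive repeats, per curve, the file life cycle:
`<name>-curve<k>_bagit.jdx` (converted data), `…_bagit.peak.jdx`
(auto-picked peaks — present only if picking ran and no manual edit
followed), `…_bagit.edit.jdx` (manual edit, which *replaces* the peak
file), plus per-curve PNG and CSV; dataset-level files are the
description text file, the original vendor file, the bag, the workbook
and two preview images. Both the underscore (`-curve1_bagit.peak.jdx`)
and dot (`-curve1.bagit.peak.jdx`) naming dialects are emitted on
request; underscore is the default. The archive inventory is a pure
function of the curve count and edit flags, which the tests verify
exhaustively for up to three curves.

The workbook has `2 + x` sheets for `x` curves: definitions, the merged
metadata (every scheme field, including missing ones, with provenance),
and one analysis sheet per curve. The writer emits minimal OOXML
(inline strings, no styling) and is checked in the tests by an
independent XML reader.

## Peak picking

`pick_peaks()` smooths the sweep current with a centred moving average
(default window 5 samples, shrunk at the edges), finds local maxima
(anodic sweeps) or minima (cathodic sweeps), and keeps those whose
topographic prominence reaches `min_prominence` (default 5 %) of the
smoothed current range. The 5 % default suppresses capacitive ripple and
noise without hiding quasi-reversible peaks; both parameters are exposed
end to end. Peak coordinates are reported from the **unsmoothed** data
at the located index, so smoothing never biases a reported potential. A
sweep flat to within rounding yields no peaks; a sweep shorter than the
window is an error. The switching-potential correction current
`i_lambda0` is deliberately a user input — determining it graphically is
the experimentalist's judgement call, and no automatic baseline fit is
attempted.

## The ingestion watcher

An instrument file is considered complete when its **size has been
stable for at least `delay` seconds** (default 300 s): some observation
at least `delay` old already shows the final size, and nothing observed
since differs. Size stability is used instead of OS file locks for
portability across instrument PCs. Completed units are queued exactly
once, de-duplicated by path plus content digest, with an injectable
clock so the tests can drive hours of watching in milliseconds. Network
transfer is out of scope; the "transfer" is delivery into a local inbox
(optionally zipping folder units).

## Problem sizes used by the tests

The test suite and the acceptance script run the reference condition
(3 cycles, 8 401 samples, ≈ 1 000 grid nodes, a few seconds) where
physics matters, and a coarser two-cycle variant (2 mV steps, 4
sub-steps) where only plumbing is exercised; workbook layout is checked
for 1–20 curves and archive inventories exhaustively for up to 3 curves.
These sizes were chosen as the smallest that still measure each claim
meaningfully.

## Known limitations

* The vendor dialects are documented stand-ins structured like the real
  formats (tagged header + CURVE tables; `key: value` prologue + CSV);
  adapters for the exact proprietary layouts would be added as further
  profiles and readers.
* Only the reversible limit is simulated; descriptor accuracy on
  quasi-reversible or chemically coupled systems is untested.
* `ipa/ipc` in direct mode inherits the zero-line bias discussed above;
  use Nicholson mode with a measured `i_lambda0` for chemically
  meaningful ratios.
* The XLSX writer targets structural fidelity (sheet count, cell
  values), not styling.
* Repository deposition (and any network interaction) is out of scope.
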
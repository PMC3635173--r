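---
title: "Methods: two-scenario CT organ dose reconstruction with shared-error propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-scenario CT organ dose reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, its numerical
choices, and the limits of what its tests demonstrate.

## The dosimetry model

### Phantoms

The reference body models are stylized: each phantom is a stack of
contiguous elliptical axial slabs (z in mm, origin at the crown, increasing
caudally) with nested elliptical tissue regions checked innermost-first —
brain inside a skull ring inside scalp, lungs and spine in the chest, colon
limbs and lumbar spine in the abdomen, iliac wings and sacrum in the
pelvis, femora in the legs. Six age classes (newborn, 1, 5, 10, 15 years,
adult) and both sexes are built from one adult template scaled axially by
stature and laterally by body mass, with age-specific head proportions and
landmark fractions from the bundled anthropometry file. This is a
deliberate surrogate for anatomically realistic NURBS/mesh hybrid phantom
families: it keeps transport at desk scale, depends on no external phantom
files, and exposes the same interface (age classes, head/chest/abdomen
landmarks, organ masses), so a more realistic geometry could be substituted
without touching the rest of the pipeline. The cost is anatomical fidelity:
absolute organ doses are plausible in magnitude and ordering but are not
validated against measured paediatric organ dose data, and no claim of
agreement with published conversion-coefficient compilations is made.

Red bone marrow is handled as the field handles it epidemiologically: the
marrow dose is a fixed-weight mean over skeletal-site doses (skull, spine,
pelvis, femora), with age-specific site fractions stored alongside the
anthropometry — an infant's marrow is skull-heavy, an adult's
spine/pelvis-heavy. Site doses are energy deposited in the site's bone
regions divided by the site mass; marrow is not resolved below the region
level (no trabecular micro-dosimetry).

Patient-to-phantom selection uses nearest reference age with ties broken
toward the *younger* class — smaller bodies receive more dose per unit
exposure, so the tie break is conservative. When height and weight are both
recorded, selection instead minimizes Euclidean distance in standardized
(height/sd, weight/sd) space over the reference family. Both stature
coordinates carry equal weight; nothing in the underlying methodology
states which should dominate, and we left them symmetric rather than
invent a preference.

### Photon transport

Transport is a single-purpose Monte Carlo kernel (C++):

* **Interactions.** Photoelectric absorption and incoherent (Compton)
  scattering, the latter sampled from the Klein–Nishina differential cross
  section by the standard two-branch rejection method; the scattered energy
  satisfies the Compton relation exactly for the sampled angle. Coherent
  scattering is excluded (its dose contribution at CT energies is small and
  it deposits no energy); the bundled attenuation tables therefore store
  photoelectric + incoherent components only, log-log interpolated.
* **Kerma approximation.** Secondary electrons deposit at the interaction
  site. At CT energies (effective 50–70 keV) electron ranges are fractions
  of a millimetre, far below organ dimensions; this is the standard
  approximation of the organ-dose literature.
* **Geometry.** Woodcock (delta) tracking against the majorant attenuation
  over the materials present — no surface intersection code, which is what
  makes arbitrary nested-ellipse stacks cheap. The material table passed to
  each run is subset to the materials actually present so the majorant
  stays tight.
* **Beam.** A rotating fan beam: per photon the source angle is uniform on
  [0, 2pi), modelling continuous rotation without projection-count
  artefacts; fan angle and z-collimation are sampled uniformly at the
  isocenter plane. The default spectrum is a single effective energy per
  tube voltage (80 to 50, 100 to 56, 120 to 62, 140 to 69 keV) —
  implementation constants, overridable by any user-supplied discrete
  spectrum. There is no bow-tie filter (flat fan); a radial weighting hook
  would slot into the source sampler.
* **Cutoff.** Photons below 2 keV deposit their residual locally and are
  banked; energy bookkeeping (emitted = deposited + escaped) holds to
  1e-9 relative per run and is asserted in the tests.
* **Reproducibility.** One RNG stream per run (splitmix-scrambled
  mt19937_64); every coefficient-table cell uses a sub-seed derived by a
  stable string hash, so any cell is reproducible in isolation, and results
  are independent of evaluation order.

### CTDIw normalization and the dose engine

Coefficients are stored as organ dose per axial rotation per mGy of CTDIw,
with CTDIw simulated in the standard 160 mm (head) / 320 mm (body) PMMA
cylinders: the mean dose along a 100 mm central/peripheral chamber scaled
to CTDI100, combined 1/3 centre + 2/3 periphery. Cells whose z lies in the
head landmark normalize against the head cylinder, others against the body
cylinder. The absolute photon-fluence calibration (photons per mAs) is a
bundled constant that cancels in the normalized coefficients.

The deterministic engine places rotations at step `collimation x pitch`
across the mapped scan interval, weighting a partial final rotation by its
fractional coverage — the helical approximation matching the axial
granularity of the coefficient tables. Coefficients are interpolated
linearly in z and linearly in log-kVp; outside the kVp grid the engine
raises an error rather than extrapolate. CTDIw per rotation comes from the
recorded CTDIw when present (tier "reported"), otherwise from a bundled
normalized-CTDIw lookup by scanner class and era (tier "era_lookup", with a
multiplicative uncertainty factor in the probabilistic path); the tier is
carried in the output. Tube-current modulation is honoured only as an
explicit per-rotation profile; when only a summary mAs exists, unknown
modulation is represented in the uncertainty model as a dose-modifying
factor PDF rather than reconstructed.

Scan-range mapping: a series with a body-region label and no usable
positions covers the region landmark exactly; absolute positions with a
localizer reference preserve the recorded length centred on the landmark.
Protocol periods are matched on calendar date with boundary dates resolving
to the earlier period (questionnaire periods are recorded with inclusive
end dates, and the earlier protocol is the conservative attribution for a
boundary-day exam).

## Missing parameters and shared errors

Each missing parameter is a PDF with a *sharing scope*. Group scope (the
default for protocol parameters) means one draw per protocol group per
realization, shared by every patient in the group — the formalization of
"everyone at this hospital in this period was imaged under the same
unknown protocol". Scanner scope is coarser: one draw per
hospital/period/scanner unit, shared across that scanner's exam-type and
age-group cells — the correct unit for the normalized-CTDIw calibration
factor, which is one physical property of the machine, not of the
protocol. Patient scope draws independently per patient (modulation
factor, stature deviation). Parameters elicited from data
follow a ladder: three or more observed values give a lognormal with their
geometric median and geometric SD truncated to era bounds; one or two give
a triangular with mode at their mean and era-default bounds; none falls
back to the bundled era-default registry (an editable YAML file with
provenance fields; its entries are plausible-practice defaults for the
synthetic study, not survey data). Post-PACS elicitations are never wider
than the pre-PACS defaults for the same parameter — knowledge does not
degrade with time — implemented by intersecting truncation bounds.
Correlation between parameters is represented only through joint discrete
rows (linkage ids drawing one row of a kVp/mAs/pitch table), not copulas:
protocols are naturally tabular and no correlation model beyond
joint selection is defensible from protocol data.

Realizations are generated cohort-wide: per realization, all shared draws
happen once per group, patient draws once per patient, then the
deterministic engine recomputes every dose. Seeds derive from
(master seed, scope key, parameter, realization index) via a stable hash,
so outputs are invariant to patient order and to which subset of patients
is computed. With `inner_reps > 1` the sampling is nested — outer draws of
the shared parameters, inner draws of patient-scope parameters — which is
what permits the exact law-of-total-variance split of dose variance into
shared and unshared components (population variances, so the two parts sum
to the total identically). Without nesting the decomposition is reported as
unavailable rather than approximated. Sampled scan lengths are rounded to
1 mm (protocol lengths are quantized by slice thickness in practice),
which also lets the engine memoize per unique parameter combination.

## Risk models

The disease model is Poisson with rate `lambda0(stratum) * (1 + beta D)`,
`D` in Gy. Stratum baselines are profiled analytically (`lambda0_s =
cases_s / sum PY(1+beta D)`), leaving a one-dimensional profile likelihood
maximized over `beta > -1/max(D)`; the 95% interval is the
profile-likelihood interval at the chi-square(1) cutoff. Strata with zero
cases drop out of the profile (their baseline profiles to zero) and are
counted. Fits that hit the search boundary, have no dose contrast, or no
cases return flagged objects rather than raising.

Two analysis strategies over a realization set are implemented side by
side, since the methodology deliberately leaves the choice open: the mean
dose per patient across realizations fitted once; and a fit per
realization, combined with likelihood weights `w_v ∝ exp(l_v - max l)` —
the point estimate is the weighted mean of the per-realization estimates
and the interval is the 2.5/97.5 percentile of the weighted mixture of
per-realization profile-likelihood distributions, evaluated on a common
grid. Shared error inflates between-realization spread, so the combined
interval is at least as wide as the mean-dose interval; that ordering is
asserted in the tests. Only likelihood weights are provided; the weight
function is the single place to plug alternatives. Formal calibration of
two-dimensional Monte Carlo intervals (coverage of the mixture interval
under repeated sampling) is out of scope.

## The synthetic study

The generator emulates the study conditions end to end: three hospitals
with PACS transitions drawn in the middle of a 1985–2010 span; exams on
patients aged 0–19 over head/chest/abdomen with protocol tables per
hospital, era, exam type and age group (kVp 100–140 pre-PACS, 80–120 post;
age-scaled mAs; pitch 1.0 in the single-slice era); per-exam phantom
selection; outcomes Poisson with a baseline of 0.02 cases per person-year
over 5–15 person-years and a true excess relative risk of 2 per Gy to red
bone marrow. The baseline is high for a paediatric population — it is
chosen once so that cohorts of a few thousand patients yield informative
likelihoods at desk scale; the power of the synthetic design, not its
realism as a cancer registry, is what the tests exercise. Ground-truth
doses are computed by the same dose engine used in reconstruction —
deliberately, so that "perfect information recovers truth" is an identity
check on the plumbing, not a physics claim; the independent physics checks
are the closed-form attenuation and Klein–Nishina oracles in the transport
tests, and a dual-route test confirms the batch kernel and the per-series
engine agree independently.

Pre-PACS masking removes every per-series technical parameter, keeping the
limited roster fields; post-PACS masking applies configurable per-field
dropout. Masking changes presence only, never values. The weighted dose
index is treated as derivable only when both CTDIvol and pitch survive,
matching what a header harvest could actually compute. Synthetic DICOM
files are valid Part 10 explicit-VR-little-endian single-frame CT objects;
absent parameters are omitted from the headers, never zero-filled, and the
test suite verifies field-identical round trips (including with pydicom as
an independent reader). Enhanced multi-frame CT objects are not parsed —
a deliberate narrowing; per-slice files are what the fixture writer emits.
Axial images are geometric phantasms (elliptical body, skull ring, lung
ellipses) with jittered sizes and Gaussian noise: the classifier contract
is feature-level (bone fraction, internal air fraction), and passing tests
show the rule cascade and segmentation features work, not that they would
survive real anatomy, contrast media or CT artefacts.

## Problem sizes and budgets

Default test/problem sizes were chosen for single-CPU runs: coefficient
tables at 1200–2000 photons per cell on a 60 mm grid for the shared
fixtures (20000 per cell on the coarse grid where geometric ordering is
asserted), cohorts of 500–2000 patients, 50–200 realizations, 100-replicate
repeated-outcome experiments for type-I behaviour (the dose design stays
fixed across replicates; only outcomes are resampled, which is the exact
conditional experiment). The acceptance script regenerates everything from
one seed at these scales in minutes.

## Known limitations

* Stylized geometry: organ doses are plausible, not benchmarked against
  published paediatric conversion coefficients.
* Flat fan (no bow-tie), mono-energetic default beams, no overranging or
  tube-start-angle effects, no contrast-medium modification (the flag is
  carried through untouched).
* Marrow dosimetry by fixed site fractions, not skeletal micro-structure.
* Single-frame DICOM only; no PACS network query; record linkage across
  hospitals is out of scope.
* Era-default PDF widths are editable registry entries, not an elicitation
  from real surveys; conclusions about real-cohort dose uncertainty should
  re-derive them from actual sources.
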
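# Era-default parameter PDFs used when a protocol group has no observed
# values for a missing acquisition parameter. Editable registry; provenance
# fields describe where each default would come from in a real deployment
# (surveys, publications, expert elicitation) -- the entries bundled here are
# plausible-practice defaults for the synthetic study, not survey data.
# Families: point(value), uniform(min,max), triangular(min,mode,max),
# lognormal(median,gsd). trunc: [lo, hi]. scope: default sharing scope.
version: 1
eras:
  pre_pacs:
    kvp:
      family: uniform
      params: {min: 100, max: 140}
      scope: group
      provenance: historical protocol surveys, axial-era practice
    mas:
      family: lognormal
      params: {median: 150, gsd: 1.6}
      trunc: [40, 400]
      scope: group
      provenance: historical protocol surveys
    pitch:
      family: triangular
      params: {min: 0.7, mode: 1.0, max: 1.6}
      scope: group
      provenance: expert elicitation, single-slice era
    scan_length_head:
      family: triangular
      params: {min: 120, mode: 160, max: 200}
      scope: group
      provenance: anatomical coverage of routine head protocols
    scan_length_chest:
      family: triangular
      params: {min: 180, mode: 250, max: 320}
      scope: group
      provenance: anatomical coverage of routine chest protocols
    scan_length_abdomen:
      family: triangular
      params: {min: 200, mode: 280, max: 360}
      scope: group
      provenance: anatomical coverage of routine abdomen protocols
    nctdiw_factor:
      family: lognormal
      params: {median: 1.0, gsd: 1.30}
      trunc: [0.5, 2.0]
      scope: scanner
      provenance: spread of normalized CTDIw across scanner models within a class
    stature_deviation:
      family: uniform
      params: {min: -10, max: 10}
      scope: patient
      provenance: stature spread around age-reference values, cm
  post_pacs:
    kvp:
      family: uniform
      params: {min: 110, max: 130}
      scope: group
      provenance: recent protocol audits
    mas:
      family: lognormal
      params: {median: 100, gsd: 1.4}
      trunc: [40, 300]
      scope: group
      provenance: recent protocol audits
    pitch:
      family: triangular
      params: {min: 0.8, mode: 1.0, max: 1.4}
      scope: group
      provenance: multi-slice era practice
    scan_length_head:
      family: triangular
      params: {min: 130, mode: 160, max: 190}
      scope: group
      provenance: anatomical coverage of routine head protocols
    scan_length_chest:
      family: triangular
      params: {min: 200, mode: 250, max: 300}
      scope: group
      provenance: anatomical coverage of routine chest protocols
    scan_length_abdomen:
      family: triangular
      params: {min: 220, mode: 280, max: 340}
      scope: group
      provenance: anatomical coverage of routine abdomen protocols
    nctdiw_factor:
      family: lognormal
      params: {median: 1.0, gsd: 1.15}
      trunc: [0.7, 1.43]
      scope: scanner
      provenance: calibrated scanner-specific CTDIw more often available
    stature_deviation:
      family: uniform
      params: {min: -5, max: 5}
      scope: patient
      provenance: height/weight fields more often recorded
    modulation_factor:
      family: triangular
      params: {min: 0.7, mode: 0.9, max: 1.0}
      scope: patient
      provenance: tube-current modulation dose reduction, unknown algorithm
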
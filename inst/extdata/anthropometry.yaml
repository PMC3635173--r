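# Reference anthropometry for the stylized phantom family.
# Heights/masses follow reference-individual compilations for the six
# age classes; landmark fractions split stature (crown origin, caudally
# increasing z) into head / neck / chest / abdomen boundaries; rbm gives
# the fixed red-bone-marrow site fractions used for marrow dosimetry.
# head_boost inflates head lateral dimensions relative to trunk scaling
# (infant heads are proportionally larger).
reference_ages:
  newborn: 0
  1y: 1
  5y: 5
  10y: 10
  15y: 15
  adult: 20
classes:
  newborn:
    height_cm: {male: 51, female: 51}
    mass_kg: {male: 3.5, female: 3.5}
    landmark_frac: {head_end: 0.25, neck_end: 0.29, chest_end: 0.55, abd_end: 0.70}
    head_boost: 1.60
    rbm: {skull: 0.27, spine: 0.36, pelvis: 0.22, femora: 0.15}
  1y:
    height_cm: {male: 76, female: 76}
    mass_kg: {male: 10, female: 10}
    landmark_frac: {head_end: 0.22, neck_end: 0.26, chest_end: 0.53, abd_end: 0.68}
    head_boost: 1.40
    rbm: {skull: 0.24, spine: 0.37, pelvis: 0.24, femora: 0.15}
  5y:
    height_cm: {male: 109, female: 109}
    mass_kg: {male: 19, female: 19}
    landmark_frac: {head_end: 0.18, neck_end: 0.22, chest_end: 0.50, abd_end: 0.65}
    head_boost: 1.20
    rbm: {skull: 0.18, spine: 0.39, pelvis: 0.28, femora: 0.15}
  10y:
    height_cm: {male: 138, female: 138}
    mass_kg: {male: 32, female: 32}
    landmark_frac: {head_end: 0.16, neck_end: 0.20, chest_end: 0.48, abd_end: 0.63}
    head_boost: 1.10
    rbm: {skull: 0.14, spine: 0.40, pelvis: 0.30, femora: 0.16}
  15y:
    height_cm: {male: 167, female: 161}
    mass_kg: {male: 56, female: 53}
    landmark_frac: {head_end: 0.14, neck_end: 0.18, chest_end: 0.46, abd_end: 0.61}
    head_boost: 1.05
    rbm: {skull: 0.10, spine: 0.42, pelvis: 0.32, femora: 0.16}
  adult:
    height_cm: {male: 176, female: 163}
    mass_kg: {male: 73, female: 60}
    landmark_frac: {head_end: 0.13, neck_end: 0.17, chest_end: 0.45, abd_end: 0.60}
    head_boost: 1.00
    rbm: {skull: 0.08, spine: 0.42, pelvis: 0.34, femora: 0.16}
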
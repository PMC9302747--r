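# Default mangrove allometric registry (assembled defaults).
#
# Whole-tree equations use the common-form power law for Indo-Pacific
# mangroves, B[kg] = 0.251 * rho * DBH[cm]^2.46 (Komiyama et al. 2005,
# J. Trop. Ecol. 21:471-477), with species wood specific gravities rho
# (g cm^-3) from the wood-density literature. Leaf and main-stem
# components are protocol-style fractions of the whole-tree power law
# (leaves ~4%, main stem ~60%) used only by the dead-tree deduction
# rules. Validity range follows the source equation (5-49 cm DBH);
# larger stems are evaluated by extrapolation and flagged.
#
# RHST rows (R. stylosa) also serve the pooled RHST_MU class; the
# hybrid R. x lamarckii (RHLA) resolves to RHAP; the unidentified
# Rhizophora class (RH_UNK) averages the three resolved Rhizophora
# models. Substitutions are applied by the registry lookup, not
# duplicated here.
models:
- species: BRGY
  component: WHOLE_TREE
  form: power
  coefficients: [0.185740, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.74
  source: Komiyama et al. 2005 common equation, rho 0.74
- species: BRGY
  component: LEAVES
  form: power
  coefficients: [0.0074296, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.74
  source: assembled default, ~4% of whole tree
- species: BRGY
  component: MAIN_STEM
  form: power
  coefficients: [0.111444, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.74
  source: assembled default, ~60% of whole tree
- species: LULI
  component: WHOLE_TREE
  form: power
  coefficients: [0.190760, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.76
  source: Komiyama et al. 2005 common equation, rho 0.76
- species: LULI
  component: LEAVES
  form: power
  coefficients: [0.0076304, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.76
  source: assembled default, ~4% of whole tree
- species: LULI
  component: MAIN_STEM
  form: power
  coefficients: [0.114456, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.76
  source: assembled default, ~60% of whole tree
- species: RHAP
  component: WHOLE_TREE
  form: power
  coefficients: [0.213350, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.85
  source: Komiyama et al. 2005 common equation, rho 0.85
- species: RHAP
  component: LEAVES
  form: power
  coefficients: [0.0085340, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.85
  source: assembled default, ~4% of whole tree
- species: RHAP
  component: MAIN_STEM
  form: power
  coefficients: [0.128010, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.85
  source: assembled default, ~60% of whole tree
- species: RHST
  component: WHOLE_TREE
  form: power
  coefficients: [0.210840, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.84
  source: Komiyama et al. 2005 common equation, rho 0.84
- species: RHST
  component: LEAVES
  form: power
  coefficients: [0.0084336, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.84
  source: assembled default, ~4% of whole tree
- species: RHST
  component: MAIN_STEM
  form: power
  coefficients: [0.126504, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.84
  source: assembled default, ~60% of whole tree
- species: SOAL
  component: WHOLE_TREE
  form: power
  coefficients: [0.128010, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.51
  source: Komiyama et al. 2005 common equation, rho 0.51
- species: SOAL
  component: LEAVES
  form: power
  coefficients: [0.0051204, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.51
  source: assembled default, ~4% of whole tree
- species: SOAL
  component: MAIN_STEM
  form: power
  coefficients: [0.076806, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.51
  source: assembled default, ~60% of whole tree
- species: XYGR
  component: WHOLE_TREE
  form: power
  coefficients: [0.153110, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.61
  source: Komiyama et al. 2005 common equation, rho 0.61
- species: XYGR
  component: LEAVES
  form: power
  coefficients: [0.0061244, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.61
  source: assembled default, ~4% of whole tree
- species: XYGR
  component: MAIN_STEM
  form: power
  coefficients: [0.0918660, 2.46]
  dbh_min: 5.0
  dbh_max: 49.0
  specific_gravity: 0.61
  source: assembled default, ~60% of whole tree
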
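# Default 14-compartment human circulation for CPR simulation.
# Closed RC-diode loop in the Babbs tradition: compliances C in mL/mmHg,
# initial (circulatory-arrest) pressures P0 in mmHg, edge resistances R
# in mmHg min/L. Compartments flagged intrathoracic receive the
# mediastinal pressure source P_M (the direct cardiac squeeze);
# the lung vascular bed receives the alveolar source P_lung instead.
# The stiff thoracic aorta and the pulmonary-vein reservoir are treated
# as pressure-shielded: their walls do not transmit the mediastinal
# squeeze, which lets the mitral valve gate a two-stage fill/eject pump
# (decompression fills the left heart from the shielded reservoir,
# compression ejects into the unexposed aorta).
compartments:
  - {name: right_heart,      C: 8.0,  P0: 7.0, intrathoracic: true,  pulmonary: false}
  - {name: pulmonary_artery, C: 4.0,  P0: 8.0, intrathoracic: true,  pulmonary: false}
  - {name: lungs,            C: 10.0, P0: 8.0, intrathoracic: false, pulmonary: true}
  - {name: pulmonary_veins,  C: 8.0,  P0: 8.0, intrathoracic: false, pulmonary: false}
  - {name: left_heart,       C: 8.0,  P0: 8.0, intrathoracic: true,  pulmonary: false}
  - {name: aorta,            C: 0.4,  P0: 8.0, intrathoracic: false, pulmonary: false}
  - {name: abdominal_aorta,  C: 2.0,  P0: 8.0, intrathoracic: false, pulmonary: false}
  - {name: carotid_arteries, C: 0.3,  P0: 8.0, intrathoracic: false, pulmonary: false}
  - {name: brain,            C: 2.0,  P0: 8.0, intrathoracic: false, pulmonary: false}
  - {name: jugular_veins,    C: 5.0,  P0: 6.0, intrathoracic: false, pulmonary: false}
  - {name: svc,              C: 3.0,  P0: 6.0, intrathoracic: true,  pulmonary: false}
  - {name: abdominal_organs, C: 30.0, P0: 6.0, intrathoracic: false, pulmonary: false}
  - {name: ivc,              C: 15.0, P0: 6.0, intrathoracic: false, pulmonary: false}
  - {name: legs,             C: 10.0, P0: 6.0, intrathoracic: false, pulmonary: false}
edges:
  - {from: svc,              to: right_heart,      R: 0.208, valve: true}
  - {from: ivc,              to: right_heart,      R: 0.208, valve: true}
  - {from: right_heart,      to: pulmonary_artery, R: 0.125, valve: true}
  - {from: pulmonary_artery, to: lungs,            R: 0.417, valve: false}
  - {from: lungs,            to: pulmonary_veins,  R: 0.417, valve: false}
  - {from: pulmonary_veins,  to: left_heart,       R: 0.208, valve: true}
  - {from: left_heart,       to: aorta,            R: 0.25,  valve: true}
  - {from: aorta,            to: abdominal_aorta,  R: 0.833, valve: false}
  - {from: aorta,            to: carotid_arteries, R: 2.5,   valve: false}
  - {from: carotid_arteries, to: brain,            R: 63.0,  valve: false}
  - {from: brain,            to: jugular_veins,    R: 63.0,  valve: false}
  - {from: jugular_veins,    to: svc,              R: 1.667, valve: true}
  - {from: abdominal_aorta,  to: abdominal_organs, R: 70.0,  valve: false}
  - {from: abdominal_organs, to: ivc,              R: 5.0,   valve: false}
  - {from: abdominal_aorta,  to: legs,             R: 88.0,  valve: false}
  - {from: legs,             to: ivc,              R: 5.0,   valve: false}
sources:
  E: 78.0         # effective chest Young's modulus, mmHg
  d0: 0.125        # anterior-posterior cardiac tissue thickness, m
  A_L: 0.008       # compressed-lung cross-sectional area, m^2
  R_airway: 20.0   # airway impedance, mmHg s/L
  C_lung: 0.01     # lung compliance, L/mmHg
  P_mouth: 0.0     # mouth pressure, mmHg
  x2_mode: volume  # vessel-expansion speed from thoracic volume rate
  A_eff: 0.01      # effective coupling area, m^2
roles:
  cardiac_output_edge: [left_heart, aorta]
  cerebral_edge: [carotid_arteries, brain]
  aorta: aorta
  right_atrium: right_heart
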
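# Adverse-event disutilities for scenario 4.
#
# The stroke-state utility decrement (0.161, applied every cycle spent in
# the stroke state) is the value used by the source analysis. The one-off
# QALY decrements per incident adverse event are a SYNTHETIC RECONSTRUCTION:
# the scenario's full disutility table is not published in an accessible
# form, so literature-typical values from published valve-replacement
# cost-effectiveness models are used instead.
stroke_state_decrement: 0.161
one_off:
  rehospitalisation: 0.010
  MI: 0.030
  major_vascular: 0.020
  bleeding: 0.030
  endocarditis: 0.040
  AKI: 0.050
  new_PPI: 0.010
  TIA: 0.020
  AF: 0.020
  PAR: 0.030
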
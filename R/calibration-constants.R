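# Frozen normalization constants, fitted once by scripts/calibrate.R:
# reference bruits (RI 0.5, HR 75 bpm, 20 seeds) at the extreme flows observed
# in the verification cohort anchor the map (FV 160 -> index ~41, FV 3025 ->
# 999); p_ref is the mean band power at FV 1000 used by the fast surrogate.
# Do not edit by hand.
.hvsi_default_cal <- list(
  p_min = 1017.214663,
  p_max = 21635.04373,
  p_ref = 7153.663404,
  id = "default-v1"
)
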
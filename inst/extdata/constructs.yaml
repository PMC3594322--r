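# Construct catalogue for the synthetic metaphase-cell generator.
#
# target_cer is the mean chromosome enrichment ratio the construct should
# show on noise-free synthetic cells; the plate enrichment multiplier is
# solved from it at load time against the chosen cell geometry
# (calibrate_profile). Targets are the published per-construct mean CERs.
# Spindle and centrosome multipliers are qualitative scene-dressing chosen
# from the described localization patterns (full-length reporter decorates
# centrosomes and spindle; free GFP shows enhanced signal around the
# spindle only); they shape the images but the calibration absorbs them, so
# the ground-truth CER is exact regardless.
constructs:
  - name: WT_1-433
    target_cer: 1.87
    spindle_enrich: 1.5
    centrosome_enrich: 2.5
  - name: GFP
    target_cer: 1.37
    spindle_enrich: 1.3
    centrosome_enrich: 1.0
  - name: WT_1-63
    target_cer: 2.45
    spindle_enrich: 1.2
    centrosome_enrich: 1.0
  - name: WT_1-110
    target_cer: 2.34
    spindle_enrich: 1.2
    centrosome_enrich: 1.0
  - name: WT_1-166
    target_cer: 2.14
    spindle_enrich: 1.2
    centrosome_enrich: 1.0
  - name: WT_1-41
    target_cer: 1.97
    spindle_enrich: 1.2
    centrosome_enrich: 1.0
  - name: WT_1-20
    target_cer: 1.55
    spindle_enrich: 1.3
    centrosome_enrich: 1.0
  - name: WT_1-15
    target_cer: 1.39
    spindle_enrich: 1.3
    centrosome_enrich: 1.0
  - name: WT_21-433
    target_cer: 1.35
    spindle_enrich: 1.5
    centrosome_enrich: 2.5
  - name: WT_42-433
    target_cer: 1.20
    spindle_enrich: 1.5
    centrosome_enrich: 2.5
  - name: R42A_1-433
    target_cer: 1.61
    spindle_enrich: 1.5
    centrosome_enrich: 2.5
  - name: dDB_1-433
    target_cer: 1.85
    spindle_enrich: 1.5
    centrosome_enrich: 2.5
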
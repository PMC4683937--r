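# Alpha-globin GRACE-PCR panel: CLCN7 two-copy reference plus HBA1/HBA2 targets.
# Product Tms are ~3 degrees C apart so the three melt transitions separate on a
# 0.2 degrees C acquisition grid. width_c is the logistic melt transition width
# used by the simulator; per_copy_amplitude is the signal one gene copy adds
# (reference primers are run at reduced concentration in the wet assay so all
# three peaks are comparable; the simulator encodes that balance directly).
reference: CLCN7
reference_copies: 2
targets: [HBA1, HBA2]
allowed_copy_states: [0, 1, 2, 3]
amplicons:
  - name: CLCN7
    tm_c: 79.4
    width_c: 0.2
    per_copy_amplitude: 1.0
    window_c: 1.2
  - name: HBA1
    tm_c: 82.2
    width_c: 0.2
    per_copy_amplitude: 1.0
    window_c: 1.2
  - name: HBA2
    tm_c: 85.2
    width_c: 0.2
    per_copy_amplitude: 1.0
    window_c: 1.2
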
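# Default two-scan UTE protocol (3 T, 0.8 mm isotropic knee acquisition).
# measurement_1: low-flip scan with minimized T1 weighting (S1)
# measurement_2: dual-echo scan, Ernst-angle condition for T1 ~ 500 ms (S2/S3)
measurement_1:
  label: "UTE S1, minimal T1 weighting"
  tr: 4.92
  fa: 3.0
  tes: [0.03]
measurement_2:
  label: "UTE dual-echo S2/S3"
  tr: 9.24
  fa: 11.0
  tes: [0.03, 2.46, 4.92]
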
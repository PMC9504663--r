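# Short-arm fractions (f_s = short-arm length / total chromosome length)
# used to convert RPHC (per-arm) positions to fractional lengths (FL,
# whole-chromosome). The study does not print its arm ratios; these are
# reconstruction choices (0.335 reproduces the stated FL = 13.4 % for
# Unigene28076 at RPHC 60.0 on chromosome 2).
chromosome	short_arm_fraction	source
2	0.335	reconstruction
6	0.40	reconstruction
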
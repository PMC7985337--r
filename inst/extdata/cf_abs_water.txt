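# Radial conversion factor CF(r) = dose in ABS phantom / dose in water,
# for an Ir-192 HDR source in a 30x30 cm ABS slab phantom.
# medium_pair: ABS/water
# valid_range_cm: 0.5 8.0
# Anchors: Monte-Carlo-derived published values; the 1.0 cm anchor is the
# ABS percentage dose at the 1 cm water normalization point (93.20%).
# Below 0.5 cm the curve is clamped; above 8.0 cm CF is taken as exactly 1
# (the ABS/water difference there is below 1.5% and treated as negligible).
0.5, 0.88
1.0, 0.932
2.1, 1.00
6.0, 1.08
8.0, 1.04
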
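# SYNTHETIC TG-43 source characterization, mHDR-v2-like geometry.
# The active length (0.35 cm) matches the mHDR-v2 source design; the
# dose-rate constant and the g_L / F tables below are a synthetic stand-in
# shaped like published Ir-192 consensus data (consensus tables are not
# redistributed in this package). Intended for testing and demonstration;
# replace with manufacturer / consensus data for clinical-grade use.
# Dialect: '#' comments; [SOURCE] key,value rows; [GL] r_cm,gL rows;
# [F] 'angles,...' header row then r,F(r,angle...) rows. Angles in degrees
# from the source long axis; F normalized to 1 at 90 degrees.
[SOURCE]
name, mHDR-v2 (synthetic tables)
active_length_cm, 0.35
dose_rate_constant, 1.109
[GL]
0.25, 0.990
0.50, 0.996
0.75, 0.999
1.00, 1.000
1.50, 1.003
2.00, 1.005
3.00, 1.006
4.00, 1.001
5.00, 0.993
6.00, 0.982
8.00, 0.948
10.00, 0.903
[F]
angles, 0, 10, 20, 30, 45, 60, 75, 90, 105, 120, 135, 150, 160, 170, 180
0.25, 0.620, 0.710, 0.810, 0.880, 0.940, 0.970, 0.990, 1.000, 0.990, 0.970, 0.940, 0.880, 0.810, 0.710, 0.620
0.50, 0.640, 0.730, 0.820, 0.890, 0.950, 0.980, 0.995, 1.000, 0.995, 0.980, 0.950, 0.890, 0.820, 0.730, 0.640
1.00, 0.660, 0.750, 0.840, 0.900, 0.950, 0.980, 0.995, 1.000, 0.995, 0.980, 0.950, 0.900, 0.840, 0.750, 0.660
2.00, 0.680, 0.770, 0.850, 0.910, 0.960, 0.980, 0.995, 1.000, 0.995, 0.980, 0.960, 0.910, 0.850, 0.770, 0.680
3.00, 0.700, 0.780, 0.860, 0.920, 0.960, 0.980, 0.995, 1.000, 0.995, 0.980, 0.960, 0.920, 0.860, 0.780, 0.700
5.00, 0.720, 0.800, 0.870, 0.920, 0.960, 0.990, 0.995, 1.000, 0.995, 0.990, 0.960, 0.920, 0.870, 0.800, 0.720
8.00, 0.740, 0.810, 0.880, 0.930, 0.970, 0.990, 0.995, 1.000, 0.995, 0.990, 0.970, 0.930, 0.880, 0.810, 0.740
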
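sample,18S,GAPDH,ACTB,TOP1,RPS29
NI_non_01,10.95,24.73,26.05,27.14,38.81
NI_non_02,11.94,27.89,28.85,28.88,37.03
NI_non_03,11.77,27.35,26.3,28.79,36.87
NI_grav_01,10.81,28.51,31.09,27.79,40.95
NI_grav_02,10.88,26.29,24.01,27.56,34.68
NI_grav_03,12.75,28.33,26.46,29.94,39.6
V1_non_01,11.62,27.02,29.29,29.68,36.33
V1_non_02,11.31,26.65,25.7,27.15,36.83
V1_non_03,13.54,28.23,27.28,28.46,39.37
V1_grav_01,12.13,28.13,29.73,26.79,39.82
V1_grav_02,10.69,27.84,28.93,28.43,39.1
V1_grav_03,14.72,26.32,23.89,25.95,38.88
V2_non_01,13.98,26.35,27.01,27.13,35.98
V2_non_02,9.96,29.3,25.93,30.53,38.42
V2_non_03,12.98,27.56,32.35,30.17,36.9
V2_grav_01,11.51,28.37,23.79,30.71,39.68
V2_grav_02,9.06,26.67,27.11,26.01,37.47
V2_grav_03,11.6,28.18,23.08,25.4,38.35
V3_non_01,12.19,28.65,25.32,28.81,38.65
V3_non_02,10.16,27.76,26.18,28.9,37.09
V3_non_03,14.01,25.82,26.06,26.02,39.95
V3_grav_01,10.62,27.96,27.09,27.42,37.43
V3_grav_02,11.82,26.84,25.81,28.63,34.98
V3_grav_03,12.21,27.03,25.9,27.35,44.24
V4_non_01,13.25,27.7,25.96,25.58,37.16
V4_non_02,12.63,26.58,25.65,27.3,36.9
V4_non_03,11.41,24.43,27.15,28.26,37.31
V4_grav_01,12.39,29.53,27.31,29.07,39.86
V4_grav_02,13.47,28.72,27.43,28.93,41.1
V4_grav_03,13.4,25.34,22.48,25.85,42.4
V5_non_01,11.56,25.72,25.22,26.38,39.36
V5_non_02,11.05,29.17,22.99,27.61,38.28
V5_non_03,12.52,28.42,23.96,26.68,40.87
V5_grav_01,12.55,27.82,26.84,28.12,41.79
V5_grav_02,13.48,30.14,23.02,28.67,38.85
V5_grav_03,13.44,31.18,27.69,27.35,38.17
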
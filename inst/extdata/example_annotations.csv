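sample,group,location
NI_non_01,NI,non-dependent
NI_non_02,NI,non-dependent
NI_non_03,NI,non-dependent
NI_grav_01,NI,gravity-dependent
NI_grav_02,NI,gravity-dependent
NI_grav_03,NI,gravity-dependent
V1_non_01,V1,non-dependent
V1_non_02,V1,non-dependent
V1_non_03,V1,non-dependent
V1_grav_01,V1,gravity-dependent
V1_grav_02,V1,gravity-dependent
V1_grav_03,V1,gravity-dependent
V2_non_01,V2,non-dependent
V2_non_02,V2,non-dependent
V2_non_03,V2,non-dependent
V2_grav_01,V2,gravity-dependent
V2_grav_02,V2,gravity-dependent
V2_grav_03,V2,gravity-dependent
V3_non_01,V3,non-dependent
V3_non_02,V3,non-dependent
V3_non_03,V3,non-dependent
V3_grav_01,V3,gravity-dependent
V3_grav_02,V3,gravity-dependent
V3_grav_03,V3,gravity-dependent
V4_non_01,V4,non-dependent
V4_non_02,V4,non-dependent
V4_non_03,V4,non-dependent
V4_grav_01,V4,gravity-dependent
V4_grav_02,V4,gravity-dependent
V4_grav_03,V4,gravity-dependent
V5_non_01,V5,non-dependent
V5_non_02,V5,non-dependent
V5_non_03,V5,non-dependent
V5_grav_01,V5,gravity-dependent
V5_grav_02,V5,gravity-dependent
V5_grav_03,V5,gravity-dependent
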
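id	group	energy_per_chain	energy_per_residue
ATTRv-I84S_closed	ATTR	-70.2	-0.669
ATTRv-I84S_open	ATTR	-55.4	-0.56
ATTRv-I84S_absent	ATTR	-62.8	-0.641
ATTRv-I84S_broken	ATTR	-60.3	-0.603
ATTRwt_heart	ATTR	-65.3	-0.725
ATTRv-V30M_heart	ATTR	-57.9	-0.622
ATTRv-V30M_eye	ATTR	-67.7	-0.698
amyloid_001	other	-58.1	-0.842
amyloid_002	other	-71.7	-0.505
amyloid_003	other	-26.4	-0.562
amyloid_004	other	-32.7	-0.584
amyloid_005	other	-40.9	-0.393
amyloid_006	other	-14.9	-0.101
amyloid_007	other	-17	-0.133
amyloid_008	other	-27.5	-0.293
amyloid_009	other	-32.7	-0.334
amyloid_010	other	-24.1	-0.548
amyloid_011	other	-44.8	-0.457
amyloid_012	other	-38.4	-0.541
amyloid_013	other	-33.1	-0.704
amyloid_014	other	-34.4	-0.8
amyloid_015	other	-36.7	-0.276
amyloid_016	other	-38.7	-0.679
amyloid_017	other	-31.4	-0.238
amyloid_018	other	-11.3	-0.079
amyloid_019	other	-34.4	-0.334
amyloid_020	other	-36.5	-0.384
amyloid_021	other	-43.5	-0.558
amyloid_022	other	-25.4	-0.339
amyloid_023	other	-28.1	-0.493
amyloid_024	other	-49.8	-0.547
amyloid_025	other	-27	-0.203
amyloid_026	other	-30.7	-0.25
amyloid_027	other	-14.1	-0.118
amyloid_028	other	-11.4	-0.085
amyloid_029	other	-38.8	-0.882
amyloid_030	other	-43.7	-0.475
amyloid_031	other	-40.6	-0.419
amyloid_032	other	-28.1	-0.195
amyloid_033	other	-25.2	-0.207
amyloid_034	other	-43.2	-0.327
amyloid_035	other	-18.4	-0.157
amyloid_036	other	-11.7	-0.095
amyloid_037	other	-28.8	-0.255
amyloid_038	other	-29	-0.309
amyloid_039	other	-17.1	-0.222
amyloid_040	other	-23.1	-0.251
amyloid_041	other	-49.2	-0.464
amyloid_042	other	-25.1	-0.302
amyloid_043	other	-41.2	-0.509
amyloid_044	other	-43.1	-0.695
amyloid_045	other	-27.6	-0.502
amyloid_046	other	-39.1	-0.521
amyloid_047	other	-30.4	-0.236
amyloid_048	other	-52.7	-0.497
amyloid_049	other	-37.5	-0.487
amyloid_050	other	-14.9	-0.233
amyloid_051	other	-71.3	-0.62
amyloid_052	other	-42	-0.385
amyloid_053	other	-60.2	-0.7
amyloid_054	other	-9.8	-0.158
amyloid_055	other	-75	-0.51
amyloid_056	other	-27.9	-0.353
amyloid_057	other	-15.2	-0.38
amyloid_058	other	-21.3	-0.181
amyloid_059	other	-52.9	-0.928
amyloid_060	other	-75	-1.442
amyloid_061	other	-30.8	-0.44
amyloid_062	other	-75	-0.568
amyloid_063	other	-46	-0.754
amyloid_064	other	-18.6	-0.168
amyloid_065	other	-26.7	-0.254
amyloid_066	other	-25.2	-0.413
amyloid_067	other	-45.6	-0.475
amyloid_068	other	-9.4	-0.069
amyloid_069	other	-35.1	-0.78
amyloid_070	other	-19.8	-0.172
amyloid_071	other	-8.2	-0.056
amyloid_072	other	-39.3	-0.281
amyloid_073	other	-12.1	-0.133
amyloid_074	other	-28.9	-0.474
amyloid_075	other	-37.6	-0.281
amyloid_076	other	-57.6	-0.811
amyloid_077	other	-8.8	-0.085
amyloid_078	other	-74.1	-1.215
amyloid_079	other	-39.8	-0.355
amyloid_080	other	-12.2	-0.177
amyloid_081	other	-24.1	-0.162
amyloid_082	other	-15.8	-0.243
amyloid_083	other	-46.6	-0.568
amyloid_084	other	-5.8	-0.089
amyloid_085	other	-57.7	-0.385
amyloid_086	other	-45.7	-0.415
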
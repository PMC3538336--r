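population,trait,MS_M,MS_E,df_M,df_E,V_A,V_E,H2
RIL1,area,0.266,2.28e-4,160,1.64e5,2.60e-4,9.78e-5,0.727
RIL1,major_axis,1.54,1.52e-3,160,1.64e5,1.50e-3,7.68e-4,0.662
RIL1,minor_axis,0.421,4.79e-4,160,1.64e5,4.12e-4,2.73e-4,0.601
RIL2,area,3.61,2.84e-4,161,2.18e6,2.69e-4,1.50e-4,0.642
RIL2,major_axis,17.3,1.57e-3,161,2.18e6,1.29e-3,9.25e-4,0.582
RIL2,minor_axis,5.93,6.26e-4,161,2.18e6,4.41e-4,4.05e-4,0.521
NIL,area,0.265,2.24e-4,91,4.77e5,5.10e-5,1.98e-4,0.205
NIL,major_axis,2.28,1.79e-3,91,4.77e5,4.40e-4,1.57e-3,0.219
NIL,minor_axis,0.403,6.02e-4,91,4.77e5,7.76e-5,5.63e-4,0.121
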
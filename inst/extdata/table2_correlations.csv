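patient_id,stratum,spo2_gt88_before,spo2_gt88_after,bipap_transition,r_pco2_cpap,r_pco2_bipap,r_spo2_cpap,r_spo2_bipap
1,LT55,No,No,Yes,0.77,-0.67,-0.69,0.48
2,GT55,Yes,Yes,Yes,-0.29,-0.60,0.30,0.52
3,GT55,No,No,Yes,0.09,-0.72,-0.25,0.02
4,NO,No,Yes,No,0.61,,0.22,
5,LT55,No,Yes,No,0.22,,0.40,
6,LT55,No,Yes,Yes,0.75,-0.68,-0.43,0.63
7,GT55,No,No,Yes,-0.08,-0.72,-0.07,0.02
8,LT55,No,Yes,No,-0.58,,-0.16,
9,GT55,Yes,Yes,Yes,0.01,-0.44,0.30,0.50
10,LT55,No,No,No,0.08,,-0.16,
11,NO,No,Yes,No,0.78,,0.69,
12,LT55,No,No,No,-0.21,,0.40,
13,LT55,No,Yes,No,0.66,,0.02,
14,LT55,No,No,Yes,0.14,-0.77,0.41,0.84
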
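wavelength_nm,n,k
310.737,1.53,1.893
320.373,1.54,1.898
331.509,1.48,1.883
342.498,1.48,1.871
354.241,1.5,1.866
367.906,1.48,1.895
381.490,1.46,1.933
397.385,1.47,1.952
413.281,1.46,1.958
430.501,1.45,1.948
450.852,1.38,1.914
471.423,1.31,1.849
495.937,1.04,1.833
520.942,0.62,2.081
548.603,0.43,2.455
582.085,0.29,2.863
616.837,0.21,3.272
659.490,0.14,3.697
704.456,0.13,4.103
756.001,0.14,4.542
821.087,0.16,5.083
891.973,0.17,5.663
984.002,0.22,6.35
1087.581,0.27,7.15
1215.531,0.35,8.145
1393.081,0.43,9.519
1610.184,0.56,11.21
1937.253,0.92,13.78
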
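# Best-fit simulated observables for the paired glucose+lactate experiments
# (joint fit, shared parameters) under the channeled (B) and well-mixed (A)
# models. The model-A glgn36 m2 value for glc_labeled is printed as 0.216 in
# the source table; kept as printed.
model,experiment,metabolite,fragment,quantity,value
B,glc_labeled,glucose,C1-C6,m0,0.514
B,glc_labeled,glucose,C1-C6,m1,0.0114
B,glc_labeled,glucose,C1-C6,m2,0.473
B,glc_labeled,glucose,C1-C6,conc,21
B,glc_labeled,glycogen,C1-C6,m0,0.683
B,glc_labeled,glycogen,C1-C6,m1,0.00767
B,glc_labeled,glycogen,C1-C6,m2,0.308
B,glc_labeled,glycogen,C1-C6,m3,0.000136
B,glc_labeled,glycogen,C1-C6,m4,0.000593
B,glc_labeled,glycogen,C1-C6,conc,0.256
B,glc_labeled,glycogen,C1-C4,m0,0.692
B,glc_labeled,glycogen,C1-C4,m1,0.00561
B,glc_labeled,glycogen,C1-C4,m2,0.302
B,glc_labeled,glycogen,C3-C6,m0,0.987
B,glc_labeled,glycogen,C3-C6,m1,0.0051
B,glc_labeled,glycogen,C3-C6,m2,0.00766
B,glc_labeled,lactate,C1-C3,m0,0.991
B,glc_labeled,lactate,C1-C3,m1,0.000974
B,glc_labeled,lactate,C1-C3,m2,0.00773
B,glc_labeled,lactate,C1-C3,m3,0.00000227
B,glc_labeled,lactate,C1-C3,conc,6.8
B,lac_labeled,glucose,C1-C6,m0,0.976
B,lac_labeled,glucose,C1-C6,m1,0.00484
B,lac_labeled,glucose,C1-C6,m2,0.00891
B,lac_labeled,glucose,C1-C6,m3,0.00996
B,lac_labeled,glucose,C1-C6,conc,20.8
B,lac_labeled,glycogen,C1-C6,m0,0.907
B,lac_labeled,glycogen,C1-C6,m1,0.0166
B,lac_labeled,glycogen,C1-C6,m2,0.0313
B,lac_labeled,glycogen,C1-C6,m3,0.0363
B,lac_labeled,glycogen,C1-C6,m4,0.00329
B,lac_labeled,glycogen,C1-C6,m5,0.00335
B,lac_labeled,glycogen,C1-C6,conc,0.256
B,lac_labeled,glycogen,C1-C4,m0,0.924
B,lac_labeled,glycogen,C1-C4,m1,0.0343
B,lac_labeled,glycogen,C1-C4,m2,0.0178
B,lac_labeled,glycogen,C1-C4,m3,0.0209
B,lac_labeled,glycogen,C1-C4,m4,0.00267
B,lac_labeled,glycogen,C3-C6,m0,0.923
B,lac_labeled,glycogen,C3-C6,m1,0.0332
B,lac_labeled,glycogen,C3-C6,m2,0.0188
B,lac_labeled,glycogen,C3-C6,m3,0.0221
B,lac_labeled,lactate,C1-C3,m0,0.621
B,lac_labeled,lactate,C1-C3,m1,0.0167
B,lac_labeled,lactate,C1-C3,m2,0.0302
B,lac_labeled,lactate,C1-C3,m3,0.332
B,lac_labeled,lactate,C1-C3,conc,6.29
A,glc_labeled,glucose,C1-C6,m0,0.514
A,glc_labeled,glucose,C1-C6,m1,0.00918
A,glc_labeled,glucose,C1-C6,m2,0.475
A,glc_labeled,glucose,C1-C6,conc,21.1
A,glc_labeled,glycogen,C1-C6,m0,0.57
A,glc_labeled,glycogen,C1-C6,m1,0.0131
A,glc_labeled,glycogen,C1-C6,m2,0.409
A,glc_labeled,glycogen,C1-C6,m3,0.00208
A,glc_labeled,glycogen,C1-C6,m4,0.00565
A,glc_labeled,glycogen,C1-C6,conc,0.196
A,glc_labeled,glycogen,C1-C4,m0,0.588
A,glc_labeled,glycogen,C1-C4,m1,0.0112
A,glc_labeled,glycogen,C1-C4,m2,0.399
A,glc_labeled,glycogen,C3-C6,m0,0.968
A,glc_labeled,glycogen,C3-C6,m1,0.0101
A,glc_labeled,glycogen,C3-C6,m2,0.216
A,glc_labeled,lactate,C1-C3,m0,0.985
A,glc_labeled,lactate,C1-C3,m1,0.00135
A,glc_labeled,lactate,C1-C3,m2,0.0141
A,glc_labeled,lactate,C1-C3,m3,0.0000436
A,glc_labeled,lactate,C1-C3,conc,6.73
A,lac_labeled,glucose,C1-C6,m0,0.984
A,lac_labeled,glucose,C1-C6,m1,0.00354
A,lac_labeled,glucose,C1-C6,m2,0.00469
A,lac_labeled,glucose,C1-C6,m3,0.00628
A,lac_labeled,glucose,C1-C6,conc,20.9
A,lac_labeled,glycogen,C1-C6,m0,0.9
A,lac_labeled,glycogen,C1-C6,m1,0.0225
A,lac_labeled,glycogen,C1-C6,m2,0.0298
A,lac_labeled,glycogen,C1-C6,m3,0.04
A,lac_labeled,glycogen,C1-C6,m4,0.00317
A,lac_labeled,glycogen,C1-C6,m5,0.00271
A,lac_labeled,glycogen,C1-C6,conc,0.196
A,lac_labeled,glycogen,C1-C4,m0,0.921
A,lac_labeled,glycogen,C1-C4,m1,0.0472
A,lac_labeled,glycogen,C1-C4,m2,0.0128
A,lac_labeled,glycogen,C1-C4,m3,0.0163
A,lac_labeled,glycogen,C1-C4,m4,0.0264
A,lac_labeled,glycogen,C3-C6,m0,0.911
A,lac_labeled,glycogen,C3-C6,m1,0.0348
A,lac_labeled,glycogen,C3-C6,m2,0.0219
A,lac_labeled,glycogen,C3-C6,m3,0.0292
A,lac_labeled,lactate,C1-C3,m0,0.608
A,lac_labeled,lactate,C1-C3,m1,0.0172
A,lac_labeled,lactate,C1-C3,m2,0.0245
A,lac_labeled,lactate,C1-C3,m3,0.35
A,lac_labeled,lactate,C1-C3,conc,6.22
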
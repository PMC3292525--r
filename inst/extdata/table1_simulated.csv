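# Best-fit simulated observables reported for the glucose-only experiment
# under the channeled (B) and well-mixed (A) hexose-phosphate models.
# The glutamate C2-C4 m1 value for model A is printed as 0.355 in the source
# table; that is a misprint for 0.0355 (it must be commensurate with the
# measured 0.0365 and the model-B value 0.0356) and is stored corrected here.
model,experiment,metabolite,fragment,quantity,value
B,glucose_only,glucose,C1-C6,m0,0.511
B,glucose_only,glucose,C1-C6,m1,0.0084
B,glucose_only,glucose,C1-C6,m2,0.481
B,glucose_only,glucose,C1-C6,conc,20.4
B,glucose_only,lactate,C1-C3,m0,0.839
B,glucose_only,lactate,C1-C3,m1,0.0237
B,glucose_only,lactate,C1-C3,m2,0.133
B,glucose_only,lactate,C1-C3,m3,0.00381
B,glucose_only,lactate,C1-C3,conc,0.959
B,glucose_only,glutamate,C2-C5,m0,0.912
B,glucose_only,glutamate,C2-C5,m1,0.0301
B,glucose_only,glutamate,C2-C5,m2,0.0574
B,glucose_only,glutamate,C2-C4,m0,0.919
B,glucose_only,glutamate,C2-C4,m1,0.0356
B,glucose_only,glutamate,C2-C4,m2,0.0454
B,glucose_only,glycogen,C1-C6,m0,0.598
B,glucose_only,glycogen,C1-C6,m1,0.0151
B,glucose_only,glycogen,C1-C6,m2,0.375
B,glucose_only,glycogen,C1-C6,m3,0.00422
B,glucose_only,glycogen,C1-C6,m4,0.00748
B,glucose_only,glycogen,C1-C6,m5,0.000432
B,glucose_only,glycogen,C1-C6,conc,0.313
B,glucose_only,glycogen,C1-C4,m0,0.627
B,glucose_only,glycogen,C1-C4,m1,0.0133
B,glucose_only,glycogen,C1-C4,m2,0.358
B,glucose_only,glycogen,C3-C6,m0,0.952
B,glucose_only,glycogen,C3-C6,m1,0.0131
B,glucose_only,glycogen,C3-C6,m2,0.0333
A,glucose_only,glucose,C1-C6,m0,0.511
A,glucose_only,glucose,C1-C6,m1,0.00839
A,glucose_only,glucose,C1-C6,m2,0.481
A,glucose_only,glucose,C1-C6,conc,20.2
A,glucose_only,lactate,C1-C3,m0,0.81
A,glucose_only,lactate,C1-C3,m1,0.0178
A,glucose_only,lactate,C1-C3,m2,0.17
A,glucose_only,lactate,C1-C3,m3,0.00145
A,glucose_only,lactate,C1-C3,conc,1.48
A,glucose_only,glutamate,C2-C5,m0,0.912
A,glucose_only,glutamate,C2-C5,m1,0.0298
A,glucose_only,glutamate,C2-C5,m2,0.0567
A,glucose_only,glutamate,C2-C4,m0,0.919
A,glucose_only,glutamate,C2-C4,m1,0.0355
A,glucose_only,glutamate,C2-C4,m2,0.0451
A,glucose_only,glycogen,C1-C6,m0,0.658
A,glucose_only,glycogen,C1-C6,m1,0.0271
A,glucose_only,glycogen,C1-C6,m2,0.299
A,glucose_only,glycogen,C1-C6,m3,0.00791
A,glucose_only,glycogen,C1-C6,m4,0.00749
A,glucose_only,glycogen,C1-C6,m5,0.000533
A,glucose_only,glycogen,C1-C6,conc,0.232
A,glucose_only,glycogen,C1-C4,m0,0.679
A,glucose_only,glycogen,C1-C4,m1,0.0297
A,glucose_only,glycogen,C1-C4,m2,0.289
A,glucose_only,glycogen,C3-C6,m0,0.951
A,glucose_only,glycogen,C3-C6,m1,0.018
A,glucose_only,glycogen,C3-C6,m2,0.0279
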
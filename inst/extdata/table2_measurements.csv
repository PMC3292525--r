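# Measured isotopologue fractions and concentrations for the paired
# glucose + lactate/pyruvate incubations: experiment glc_labeled has 20 mM
# glucose (50% [1,2-13C2]) + 10 mM lactate/pyruvate (9:1) unlabeled;
# experiment lac_labeled has the same media with lactate enriched 50% in
# [U-13C3]lactate instead. 21 + 26 = 47 rows. "--" entries of the source
# table (unmeasured channels) are omitted.
experiment,metabolite,fragment,quantity,mean,sd,units
glc_labeled,glucose,C1-C6,m0,0.532,0.0098,fraction
glc_labeled,glucose,C1-C6,m1,0.00846,0.0022,fraction
glc_labeled,glucose,C1-C6,m2,0.459,0.0103,fraction
glc_labeled,glucose,C1-C6,conc,20.6,2.91,mM
glc_labeled,glycogen,C1-C6,m0,0.681,0.032,fraction
glc_labeled,glycogen,C1-C6,m1,0.0119,0.031,fraction
glc_labeled,glycogen,C1-C6,m2,0.302,0.031,fraction
glc_labeled,glycogen,C1-C6,m3,0.0017,0.001,fraction
glc_labeled,glycogen,C1-C6,m4,0.0032,0.0016,fraction
glc_labeled,glycogen,C1-C6,conc,0.263,0.084,mg_per_mL
glc_labeled,glycogen,C1-C4,m0,0.678,0.032,fraction
glc_labeled,glycogen,C1-C4,m1,0.016,0.0046,fraction
glc_labeled,glycogen,C1-C4,m2,0.3,0.032,fraction
glc_labeled,glycogen,C3-C6,m0,0.98,0.0101,fraction
glc_labeled,glycogen,C3-C6,m1,0.00408,0.0018,fraction
glc_labeled,glycogen,C3-C6,m2,0.0139,0.0078,fraction
glc_labeled,lactate,C1-C3,m0,0.974,0.026,fraction
glc_labeled,lactate,C1-C3,m1,0.0026,0.0019,fraction
glc_labeled,lactate,C1-C3,m2,0.0094,0.0037,fraction
glc_labeled,lactate,C1-C3,m3,0.00136,0.023,fraction
glc_labeled,lactate,C1-C3,conc,6.18,0.75,mM
lac_labeled,glucose,C1-C6,m0,0.979,0.01,fraction
lac_labeled,glucose,C1-C6,m1,0.0063,0.0055,fraction
lac_labeled,glucose,C1-C6,m2,0.0055,0.0064,fraction
lac_labeled,glucose,C1-C6,m3,0.0064,0.0016,fraction
lac_labeled,glucose,C1-C6,conc,20.9,2.22,mM
lac_labeled,glycogen,C1-C6,m0,0.909,0.026,fraction
lac_labeled,glycogen,C1-C6,m1,0.017,0.0066,fraction
lac_labeled,glycogen,C1-C6,m2,0.038,0.01,fraction
lac_labeled,glycogen,C1-C6,m3,0.0273,0.0071,fraction
lac_labeled,glycogen,C1-C6,m4,0.0036,0.0016,fraction
lac_labeled,glycogen,C1-C6,m5,0.003,0.014,fraction
lac_labeled,glycogen,C1-C6,conc,0.262,0.0691,mg_per_mL
lac_labeled,glycogen,C1-C4,m0,0.93,0.024,fraction
lac_labeled,glycogen,C1-C4,m1,0.033,0.009,fraction
lac_labeled,glycogen,C1-C4,m2,0.019,0.0079,fraction
lac_labeled,glycogen,C1-C4,m3,0.014,0.005,fraction
lac_labeled,glycogen,C1-C4,m4,0.004,0.003,fraction
lac_labeled,glycogen,C3-C6,m0,0.924,0.024,fraction
lac_labeled,glycogen,C3-C6,m1,0.0265,0.007,fraction
lac_labeled,glycogen,C3-C6,m2,0.027,0.0081,fraction
lac_labeled,glycogen,C3-C6,m3,0.021,0.0067,fraction
lac_labeled,lactate,C1-C3,m0,0.636,0.017,fraction
lac_labeled,lactate,C1-C3,m1,0.0166,0.0025,fraction
lac_labeled,lactate,C1-C3,m2,0.0318,0.0035,fraction
lac_labeled,lactate,C1-C3,m3,0.316,0.0213,fraction
lac_labeled,lactate,C1-C3,conc,3.18,0.43,mM
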
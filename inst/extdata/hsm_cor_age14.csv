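mode,HSM1,HSM2,HSM3,HSM4,HSM5,HSM6,HSM7,HSM8,HSM9,HSM10
HSM1,1,0.1853,0.0371,0.0375,0.4698,-0.198,0.1578,-0.272,-0.2019,-0.1227
HSM2,0.1853,1,0.4216,0.131,0.3872,0.0883,0.054,-0.118,0.3098,-0.1471
HSM3,0.0371,0.4216,1,0.2081,0.1451,-0.0381,0.1772,0.144,0.2597,-0.1564
HSM4,0.0375,0.131,0.2081,1,0.0924,-0.1778,0.248,0.1602,0.2208,-0.2277
HSM5,0.4698,0.3872,0.1451,0.0924,1,-0.2271,0.0095,-0.0648,0.3164,-0.0647
HSM6,-0.198,0.0883,-0.0381,-0.1778,-0.2271,1,-0.0972,0.1324,-0.2759,-0.0347
HSM7,0.1578,0.054,0.1772,0.248,0.0095,-0.0972,1,-0.3302,0.2572,0.0019
HSM8,-0.272,-0.118,0.144,0.1602,-0.0648,0.1324,-0.3302,1,-0.191,0.0862
HSM9,-0.2019,0.3098,0.2597,0.2208,0.3164,-0.2759,0.2572,-0.191,1,-0.1126
HSM10,-0.1227,-0.1471,-0.1564,-0.2277,-0.0647,-0.0347,0.0019,0.0862,-0.1126,1
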
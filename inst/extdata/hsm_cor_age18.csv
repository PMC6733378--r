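mode,HSM1,HSM2,HSM3,HSM4,HSM5,HSM6,HSM7,HSM8,HSM9,HSM10
HSM1,1,0.141,0.2264,-0.0047,0.4621,-0.2515,0.0537,-0.1779,-0.1618,-0.0226
HSM2,0.141,1,0.3793,0.1983,0.4458,-0.1167,0.1083,-0.1985,0.3159,-0.0712
HSM3,0.2264,0.3793,1,0.4535,0.1827,-0.1872,0.3169,-0.0169,0.0756,-0.1303
HSM4,-0.0047,0.1983,0.4535,1,0.0864,-0.1524,0.1849,0.204,0.1695,-0.2213
HSM5,0.4621,0.4458,0.1827,0.0864,1,-0.3191,0.0347,-0.1862,0.4001,-0.0575
HSM6,-0.2515,-0.1167,-0.1872,-0.1524,-0.3191,1,-0.1257,0.1897,-0.3383,-0.0189
HSM7,0.0537,0.1083,0.3169,0.1849,0.0347,-0.1257,1,-0.1477,0.2756,0.1138
HSM8,-0.1779,-0.1985,-0.0169,0.204,-0.1862,0.1897,-0.1477,1,-0.1628,0.1194
HSM9,-0.1618,0.3159,0.0756,0.1695,0.4001,-0.3383,0.2756,-0.1628,1,-0.0967
HSM10,-0.0226,-0.0712,-0.1303,-0.2213,-0.0575,-0.0189,0.1138,0.1194,-0.0967,1
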
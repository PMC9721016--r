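# Synthetic stand-in list of 76 universal single-copy gene (USCG) family IDs.
# A representative set of universal single-copy COG families (ribosomal
# proteins, tRNA synthetases, translation factors and other core machinery);
# marker protein sequences are user-supplied. One family ID per line.
COG0012
COG0013
COG0016
COG0018
COG0030
COG0041
COG0046
COG0048
COG0049
COG0051
COG0052
COG0060
COG0064
COG0080
COG0081
COG0085
COG0086
COG0087
COG0088
COG0089
COG0090
COG0091
COG0092
COG0093
COG0094
COG0096
COG0097
COG0098
COG0099
COG0100
COG0102
COG0103
COG0105
COG0124
COG0126
COG0127
COG0130
COG0149
COG0150
COG0164
COG0172
COG0180
COG0184
COG0185
COG0186
COG0197
COG0200
COG0201
COG0202
COG0215
COG0216
COG0233
COG0244
COG0255
COG0256
COG0343
COG0361
COG0441
COG0442
COG0443
COG0480
COG0481
COG0495
COG0504
COG0519
COG0522
COG0525
COG0532
COG0533
COG0541
COG0552
COG0691
COG0858
COG1358
COG1841
COG2051
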
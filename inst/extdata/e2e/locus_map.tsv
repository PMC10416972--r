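locus_id	gene_symbol
gene00001_L1	gene00001
gene00002_L1	gene00002
gene00003_L1	gene00003
gene00004_L1	gene00004
gene00005_L1	gene00005
gene00006_L1	gene00006
gene00007_L1	gene00007
gene00008_L1	gene00008
gene00009_L1	gene00009
gene00010_L1	gene00010
gene00011_L1	gene00011
gene00012_L1	gene00012
gene00013_L1	gene00013
gene00014_L1	gene00014
gene00015_L1	gene00015
gene00016_L1	gene00016
gene00017_L1	gene00017
gene00018_L1	gene00018
gene00019_L1	gene00019
gene00020_L1	gene00020
gene00021_L1	gene00021
gene00022_L1	gene00022
gene00023_L1	gene00023
gene00024_L1	gene00024
gene00025_L1	gene00025
gene00026_L1	gene00026
gene00027_L1	gene00027
gene00028_L1	gene00028
gene00029_L1	gene00029
gene00030_L1	gene00030
gene00031_L1	gene00031
gene00032_L1	gene00032
gene00033_L1	gene00033
gene00034_L1	gene00034
gene00035_L1	gene00035
gene00036_L1	gene00036
gene00037_L1	gene00037
gene00038_L1	gene00038
gene00039_L1	gene00039
gene00040_L1	gene00040
gene00041_L1	gene00041
gene00042_L1	gene00042
gene00043_L1	gene00043
gene00044_L1	gene00044
gene00045_L1	gene00045
gene00046_L1	gene00046
gene00047_L1	gene00047
gene00048_L1	gene00048
gene00049_L1	gene00049
gene00050_L1	gene00050
gene00051_L1	gene00051
gene00052_L1	gene00052
gene00053_L1	gene00053
gene00054_L1	gene00054
gene00055_L1	gene00055
gene00056_L1	gene00056
gene00057_L1	gene00057
gene00058_L1	gene00058
gene00059_L1	gene00059
gene00060_L1	gene00060
gene00061_L1	gene00061
gene00062_L1	gene00062
gene00063_L1	gene00063
gene00064_L1	gene00064
gene00065_L1	gene00065
gene00066_L1	gene00066
gene00067_L1	gene00067
gene00068_L1	gene00068
gene00069_L1	gene00069
gene00070_L1	gene00070
gene00071_L1	gene00071
gene00072_L1	gene00072
gene00073_L1	gene00073
gene00074_L1	gene00074
gene00075_L1	gene00075
gene00076_L1	gene00076
gene00077_L1	gene00077
gene00078_L1	gene00078
gene00079_L1	gene00079
gene00080_L1	gene00080
gene00081_L1	gene00081
gene00082_L1	gene00082
gene00083_L1	gene00083
gene00084_L1	gene00084
gene00085_L1	gene00085
gene00086_L1	gene00086
gene00087_L1	gene00087
gene00088_L1	gene00088
gene00089_L1	gene00089
gene00090_L1	gene00090
gene00091_L1	gene00091
gene00092_L1	gene00092
gene00093_L1	gene00093
gene00094_L1	gene00094
gene00095_L1	gene00095
gene00096_L1	gene00096
gene00097_L1	gene00097
gene00098_L1	gene00098
gene00099_L1	gene00099
gene00100_L1	gene00100
gene00101_L1	gene00101
gene00102_L1	gene00102
gene00103_L1	gene00103
gene00104_L1	gene00104
gene00105_L1	gene00105
gene00106_L1	gene00106
gene00107_L1	gene00107
gene00108_L1	gene00108
gene00109_L1	gene00109
gene00110_L1	gene00110
gene00111_L1	gene00111
gene00112_L1	gene00112
gene00113_L1	gene00113
gene00114_L1	gene00114
gene00115_L1	gene00115
gene00116_L1	gene00116
gene00117_L1	gene00117
gene00118_L1	gene00118
gene00119_L1	gene00119
gene00120_L1	gene00120
gene00121_L1	gene00121
gene00122_L1	gene00122
gene00123_L1	gene00123
gene00124_L1	gene00124
gene00125_L1	gene00125
gene00126_L1	gene00126
gene00127_L1	gene00127
gene00128_L1	gene00128
gene00129_L1	gene00129
gene00130_L1	gene00130
gene00131_L1	gene00131
gene00132_L1	gene00132
gene00133_L1	gene00133
gene00134_L1	gene00134
gene00135_L1	gene00135
gene00136_L1	gene00136
gene00136_L2	gene00136
gene00136_L3	gene00136
gene00137_L1	gene00137
gene00138_L1	gene00138
gene00139_L1	gene00139
gene00140_L1	gene00140
gene00141_L1	gene00141
gene00142_L1	gene00142
gene00143_L1	gene00143
gene00144_L1	gene00144
gene00145_L1	gene00145
gene00146_L1	gene00146
gene00146_L2	gene00146
gene00146_L3	gene00146
gene00147_L1	gene00147
gene00148_L1	gene00148
gene00149_L1	gene00149
gene00150_L1	gene00150
gene00151_L1	gene00151
gene00152_L1	gene00152
gene00153_L1	gene00153
gene00154_L1	gene00154
gene00155_L1	gene00155
gene00156_L1	gene00156
gene00157_L1	gene00157
gene00158_L1	gene00158
gene00158_L2	gene00158
gene00159_L1	gene00159
gene00160_L1	gene00160
gene00160_L2	gene00160
gene00161_L1	gene00161
gene00162_L1	gene00162
gene00163_L1	gene00163
gene00164_L1	gene00164
gene00165_L1	gene00165
gene00166_L1	gene00166
gene00167_L1	gene00167
gene00168_L1	gene00168
gene00169_L1	gene00169
gene00170_L1	gene00170
gene00171_L1	gene00171
gene00172_L1	gene00172
gene00173_L1	gene00173
gene00174_L1	gene00174
gene00175_L1	gene00175
gene00176_L1	gene00176
gene00177_L1	gene00177
gene00178_L1	gene00178
gene00179_L1	gene00179
gene00180_L1	gene00180
gene00181_L1	gene00181
gene00182_L1	gene00182
gene00183_L1	gene00183
gene00184_L1	gene00184
gene00185_L1	gene00185
gene00186_L1	gene00186
gene00187_L1	gene00187
gene00188_L1	gene00188
gene00189_L1	gene00189
gene00190_L1	gene00190
gene00191_L1	gene00191
gene00192_L1	gene00192
gene00193_L1	gene00193
gene00194_L1	gene00194
gene00195_L1	gene00195
gene00196_L1	gene00196
gene00197_L1	gene00197
gene00198_L1	gene00198
gene00199_L1	gene00199
gene00200_L1	gene00200
gene00201_L1	gene00201
gene00202_L1	gene00202
gene00203_L1	gene00203
gene00204_L1	gene00204
gene00205_L1	gene00205
gene00206_L1	gene00206
gene00207_L1	gene00207
gene00208_L1	gene00208
gene00209_L1	gene00209
gene00210_L1	gene00210
gene00211_L1	gene00211
gene00212_L1	gene00212
gene00213_L1	gene00213
gene00214_L1	gene00214
gene00215_L1	gene00215
gene00216_L1	gene00216
gene00217_L1	gene00217
gene00218_L1	gene00218
gene00219_L1	gene00219
gene00220_L1	gene00220
gene00221_L1	gene00221
gene00222_L1	gene00222
gene00223_L1	gene00223
gene00224_L1	gene00224
gene00225_L1	gene00225
gene00226_L1	gene00226
gene00227_L1	gene00227
gene00228_L1	gene00228
gene00229_L1	gene00229
gene00230_L1	gene00230
gene00231_L1	gene00231
gene00232_L1	gene00232
gene00233_L1	gene00233
gene00234_L1	gene00234
gene00235_L1	gene00235
gene00236_L1	gene00236
gene00237_L1	gene00237
gene00238_L1	gene00238
gene00239_L1	gene00239
gene00240_L1	gene00240
gene00241_L1	gene00241
gene00242_L1	gene00242
gene00243_L1	gene00243
gene00244_L1	gene00244
gene00244_L2	gene00244
gene00245_L1	gene00245
gene00246_L1	gene00246
gene00247_L1	gene00247
gene00248_L1	gene00248
gene00249_L1	gene00249
gene00250_L1	gene00250
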
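target	fraction	condition	replicate	cq
gene00024	nuclear	control	1	21.994372935732
gene00047	nuclear	control	1	21.7638093378852
gene00049	nuclear	control	1	21.9271048714915
Malat1	nuclear	control	1	18.0697779339943
gene00024	nuclear	control	2	21.8643852890623
gene00047	nuclear	control	2	21.9583850802841
gene00049	nuclear	control	2	22.0579651622258
Malat1	nuclear	control	2	17.9909393824299
gene00024	nuclear	control	3	21.8970730358253
gene00047	nuclear	control	3	21.7140794818126
gene00049	nuclear	control	3	22.2705639630775
Malat1	nuclear	control	3	17.8549690676428
gene00024	nuclear	repeat	1	21.1970322613304
gene00047	nuclear	repeat	1	21.4160406239513
gene00049	nuclear	repeat	1	21.3349486571753
Malat1	nuclear	repeat	1	18.3096463095701
gene00024	nuclear	repeat	2	21.4703916687647
gene00047	nuclear	repeat	2	21.0022749760469
gene00049	nuclear	repeat	2	21.2803954709313
Malat1	nuclear	repeat	2	17.8918530248357
gene00024	nuclear	repeat	3	21.2261436658063
gene00047	nuclear	repeat	3	21.3601372607392
gene00049	nuclear	repeat	3	21.1955045148398
Malat1	nuclear	repeat	3	17.9984858954386
gene00024	cytoplasmic	control	1	22.0874193835787
gene00047	cytoplasmic	control	1	21.9560067494871
gene00049	cytoplasmic	control	1	21.7908426421204
GAPDH	cytoplasmic	control	1	17.9872377431472
gene00024	cytoplasmic	control	2	21.8967856979023
gene00047	cytoplasmic	control	2	21.8835217078199
gene00049	cytoplasmic	control	2	22.2616348586302
GAPDH	cytoplasmic	control	2	18.0684833269106
gene00024	cytoplasmic	control	3	21.9822735594595
gene00047	cytoplasmic	control	3	22.25131178082
gene00049	cytoplasmic	control	3	21.8261557192127
GAPDH	cytoplasmic	control	3	17.993908599955
gene00024	cytoplasmic	repeat	1	22.9133364444292
gene00047	cytoplasmic	repeat	1	22.9768199931585
gene00049	cytoplasmic	repeat	1	22.8828529550903
GAPDH	cytoplasmic	repeat	1	18.0471853417792
gene00024	cytoplasmic	repeat	2	23.0323541127077
gene00047	cytoplasmic	repeat	2	22.6878279330476
gene00049	cytoplasmic	repeat	2	22.6128905963803
GAPDH	cytoplasmic	repeat	2	18.0822733363455
gene00024	cytoplasmic	repeat	3	22.62874204619
gene00047	cytoplasmic	repeat	3	22.8293105237307
gene00049	cytoplasmic	repeat	3	22.8082149041957
GAPDH	cytoplasmic	repeat	3	17.9634899325482
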
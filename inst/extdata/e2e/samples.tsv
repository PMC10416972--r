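sample_id	condition	fraction	replicate
ctrl_nuc_r1	control	nuclear	1
ctrl_nuc_r2	control	nuclear	2
ctrl_nuc_r3	control	nuclear	3
ctrl_cyt_r1	control	cytoplasmic	1
ctrl_cyt_r2	control	cytoplasmic	2
ctrl_cyt_r3	control	cytoplasmic	3
rep_nuc_r1	repeat	nuclear	1
rep_nuc_r2	repeat	nuclear	2
rep_nuc_r3	repeat	nuclear	3
rep_cyt_r1	repeat	cytoplasmic	1
rep_cyt_r2	repeat	cytoplasmic	2
rep_cyt_r3	repeat	cytoplasmic	3
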
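region	aa_start	aa_end
N-terminus	1	124
IS1-S4	125	262
IS5	263	282
IS5-6 linker	283	362
IS6	363	387
I-II linker	388	553
IIS1-S6	554	800
II-III linker	801	932
IIIS1-S6	933	1180
III-IV linker	1181	1220
IVS1-S3	1221	1340
IVS3-4 linker	1341	1360
IVS4	1361	1385
IVS4-5 linker	1386	1420
IVS5-S6	1421	1570
C-terminus	1571	2221
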
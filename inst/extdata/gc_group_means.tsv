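# Published group means for human promoters split by core-promoter GC
# content (low: GC < 50%, high: GC >= 50%): average expression breadth
# (FANTOM5 tissues, 10 TPM cutoff) and average bound TF count.
group	mean_boe	mean_tfbs	n
low_gc	0.099	2.29	5650
high_gc	0.3379	9.55	25710
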
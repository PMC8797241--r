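group	term	estimate	std_error	t_value	p_value
intercept	(Intercept)	-0.150	0.011	-13.9	5.1e-43
sample_count	log10_samples	0.2894	0.0072	40.1	8.5e-295
batch_count	log10_batches	-0.0302	0.0081	-3.7	0.00019
species	mouse	0.0462	0.0035	13.3	3.0e-39
normalization	Rlog	0.0231	0.0060	3.9	0.00012
normalization	CPM	0.0318	0.0060	5.3	1.2e-07
normalization	TMM	0.0540	0.0060	9.0	3.0e-19
normalization	Med	0.0638	0.0060	10.7	3.9e-26
normalization	UQ	0.0782	0.0060	13.1	3.4e-38
correction	linear	0.0412	0.0042	9.7	4.1e-22
correction	combat	0.0468	0.0042	11.1	5.4e-28
correlation	spearman	-0.0107	0.0035	-3.1	0.0019
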
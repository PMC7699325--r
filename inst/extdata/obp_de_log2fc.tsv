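id	comparison	log2FC
Hirr_10315	fh_vs_fb	8.04
Hirr_11611	fh_vs_fb	3.95
Hirr_14454	fh_vs_fb	12.98
Hirr_1669	fh_vs_fb	6.99
Hirr_2780	fh_vs_fb	7.67
Hirr_4331	fh_vs_fb	11.84
Hirr_4332	fh_vs_fb	5.43
Hirr_5093	fh_vs_fb	3.82
Hirr_5094	fh_vs_fb	9.55
Hirr_5095	fh_vs_fb	8.73
Hirr_577	fh_vs_fb	5.92
Hirr_7363	fh_vs_fb	3.85
Hirr_7975	fh_vs_fb	2.69
Hirr_8159	fh_vs_fb	2.06
Hirr_9170	fh_vs_fb	8.87
Hirr_9619	fh_vs_fb	8.61
Hirr_9620	fh_vs_fb	8.35
Hirr_996	fh_vs_fb	9.19
Hirr_10749	fh_vs_fb	-2.1
Hirr_1085	fh_vs_fb	-5.06
Hirr_12458	fh_vs_fb	-3.04
Hirr_223	fh_vs_fb	-2.82
Hirr_22727	fh_vs_fb	-3.09
Hirr_23217	fh_vs_fb	-2.19
Hirr_326	fh_vs_fb	-3.95
Hirr_10315	mh_vs_mb	8.21
Hirr_11611	mh_vs_mb	3.64
Hirr_14454	mh_vs_mb	14.15
Hirr_1669	mh_vs_mb	3.15
Hirr_18675	mh_vs_mb	2.38
Hirr_2780	mh_vs_mb	7.86
Hirr_4331	mh_vs_mb	12.01
Hirr_4332	mh_vs_mb	3.99
Hirr_5093	mh_vs_mb	3.87
Hirr_5094	mh_vs_mb	9.09
Hirr_5095	mh_vs_mb	7.18
Hirr_5676	mh_vs_mb	2.6
Hirr_577	mh_vs_mb	3.8
Hirr_7363	mh_vs_mb	5.11
Hirr_9170	mh_vs_mb	9.14
Hirr_9619	mh_vs_mb	9.2
Hirr_9620	mh_vs_mb	8.58
Hirr_996	mh_vs_mb	9.6
Hirr_10749	mh_vs_mb	-3.02
Hirr_1085	mh_vs_mb	-2.61
Hirr_12458	mh_vs_mb	-6.25
Hirr_223	mh_vs_mb	-2.68
Hirr_22727	mh_vs_mb	-3.6
Hirr_22826	mh_vs_mb	-2.68
Hirr_23217	mh_vs_mb	-5.08
Hirr_326	mh_vs_mb	-3.55
Hirr_23217	fh_vs_mh	3.91
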
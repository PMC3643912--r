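gene	stage	rpkm_xx	rpkm_xy
foxh1	5	0.00	0.28
foxh1	30	1.27	0.76
foxh1	90	66.32	2.92
foxh1	180	70.19	2.86
foxj1a	5	0.67	2.90
foxj1a	30	1.38	1.18
foxj1a	90	0.07	81.15
foxj1a	180	0.02	103.15
42sp50	5	0.18	0.62
42sp50	30	10.99	13.36
42sp50	90	1127.70	26.33
42sp50	180	363.13	14.83
eef1a1b	5	3.78	8.34
eef1a1b	30	59.64	23.55
eef1a1b	90	5.92	497.17
eef1a1b	180	0.67	475.29
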
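FPR	DCA	DCN	IBO_SVM
0.02	0.72	0.83	0.93
0.04	0.76	0.86	0.95
0.06	0.77	0.865	0.965
0.08	0.783	0.870	0.98
1	0.790	0.890	1
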
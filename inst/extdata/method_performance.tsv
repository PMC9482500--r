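method	precision	recall	f_measure	specificity	accuracy
DCA	89.75	70	80.92	69.45	83.50
DCN	90.94	76.66	85.91	75.61	86.75
IBO_SVM	91.59	90.66	91.13	90.5	91.56
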
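# 16-gene recurrence-score panel (reference genes excluded)
AURKA
BAG1
BCL2
BIRC5
CCNB1
CD68
CTSL2
ERBB2
ESR1
GRB7
GSTM1
MKI67
MMP11
MYBL2
PGR
SCUBE2
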
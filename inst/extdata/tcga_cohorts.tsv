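cohort	samples
BRCA	775
KIRC	219
COAD	84
UCEC	247
GBM	290
LUSC	176
OV	151
READ	38
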
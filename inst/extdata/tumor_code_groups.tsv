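code	group
BLCA	bladder
BRCA	breast
GBM	glioma
LUAD	lung
LUSC	lung
CRC	colorectal
UCEC	endometrial
OV	ovarian
KIRC	kidney
HNSC	head_and_neck
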
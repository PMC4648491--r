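phrase	codes
bladder	BLCA
bladder cancer	BLCA
breast	BRCA
breast cancer	BRCA
glioma	GBM
glioblastoma	GBM
gbm	GBM
lung adenocarcinoma	LUAD
lung squamous cell carcinoma	LUSC
non-small cell lung cancer	LUAD,LUSC
lung cancer	LUAD,LUSC
crc	CRC
colorectal	CRC
colorectal cancer	CRC
ovarian	OV
ovarian cancer	OV
renal cell carcinoma	KIRC
kidney renal cell carcinoma	KIRC
endometrial	UCEC
endometrial cancer	UCEC
melanoma	SKCM
multiple myeloma	MM
basal cell carcinoma	BCC
prostate	PRAD
prostate cancer	PRAD
testicular germ cell	TGCT
cll	CLL
chronic lymphocytic leukemia	CLL
all	ALL
acute lymphoblastic leukemia	ALL
nasopharyngeal carcinoma	NPC
hodgkin's lymphoma	HL
gallbladder	GBC
wilms tumor	WT
pancreatic	PAAD
head and neck squamous cell carcinoma	HNSC
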
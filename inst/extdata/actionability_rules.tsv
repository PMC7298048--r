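source	gene	class	variant	tier
genomic	PIK3CA	hotspot-mutation	H1047R	clinical
genomic	PIK3CA	hotspot-mutation	E545K	clinical
genomic	ERBB2	hotspot-mutation	L755S	clinical
genomic	FGFR1	amplification		preclinical
genomic	MYC	amplification		preclinical
genomic	MDM2	amplification		preclinical
genomic	ATM	truncating		preclinical
genomic	ARID1A	truncating		preclinical
genomic	CDH1	truncating		preclinical
genomic	PIK3R1	truncating		preclinical
genomic	PTEN	deletion		preclinical
genomic	INPP4B	deletion		preclinical
expression	AR	outlier-high		clinical
expression	CD274	outlier-high		clinical
expression	FGFR1	outlier-high		preclinical
protein	CHEK1	outlier-high		preclinical
protein	CHEK2	outlier-high		preclinical
protein	FASN	outlier-high		preclinical
protein	PTK2	outlier-high		preclinical
clinical-receptor	ER	receptor-positive		clinical
clinical-receptor	HER2	receptor-positive		clinical
clinical-receptor	BRCA1/2	germline		clinical
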
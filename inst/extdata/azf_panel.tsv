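probe_id	target_locus	region	position_bp	baseline_copies	is_reference
USP9Y_01	USP9Y	AZFa	12701000	1	FALSE
USP9Y_02	USP9Y	AZFa	12726000	1	FALSE
USP9Y_03	USP9Y	AZFa	12751000	1	FALSE
DDX3Y_01	DDX3Y	AZFa	12904000	1	FALSE
DDX3Y_02	DDX3Y	AZFa	12929000	1	FALSE
DDX3Y_03	DDX3Y	AZFa	12954000	1	FALSE
HSFY_01	HSFY	AZFb	20581000	2	FALSE
HSFY_02	HSFY	AZFb	20606000	2	FALSE
RBMY1J_01	RBMY1J	AZFb	21511000	1	FALSE
RBMY1_01	RBMY1	AZFb	21534000	6	FALSE
RBMY1_02	RBMY1	AZFb	21559000	6	FALSE
RBMY1_03	RBMY1	AZFb	21584000	6	FALSE
RBMY1_04	RBMY1	AZFb	21609000	6	FALSE
KDM5D_01	KDM5D	AZFb	21868000	1	FALSE
PRY_01	PRY	AZFb	22102000	2	FALSE
PRY_02	PRY	AZFb	22127000	2	FALSE
EIF1AY_01	EIF1AY	AZFb	22740000	1	FALSE
EIF1AY_02	EIF1AY	AZFb	22765000	1	FALSE
DAZ_01	DAZ	AZFc	23202000	4	FALSE
DAZ_02	DAZ	AZFc	23852000	4	FALSE
DAZ_03	DAZ	AZFc	24502000	4	FALSE
DAZ_04	DAZ	AZFc	25152000	4	FALSE
BPY2_01	BPY2	AZFc	23551000	3	FALSE
BPY2_02	BPY2	AZFc	24501000	3	FALSE
BPY2_03	BPY2	AZFc	25451000	3	FALSE
BPY2_04	BPY2	AZFc	26401000	3	FALSE
CDY1_01	CDY1	AZFc	23704000	2	FALSE
CDY1_02	CDY1	AZFc	24804000	2	FALSE
CDY1_03	CDY1	AZFc	25904000	2	FALSE
GOLGA2LY_01	GOLGA2LY	AZFc	23860000	2	FALSE
GOLGA2LY_02	GOLGA2LY	AZFc	24760000	2	FALSE
GOLGA2LY_03	GOLGA2LY	AZFc	25660000	2	FALSE
CSPG4LY_01	CSPG4LY	AZFc	24012000	2	FALSE
CSPG4LY_02	CSPG4LY	AZFc	24812000	2	FALSE
TTTY4_01	TTTY4	AZFc	24166000	3	FALSE
TTTY4_02	TTTY4	AZFc	24866000	3	FALSE
TTTY4_03	TTTY4	AZFc	25566000	3	FALSE
TTTY17_01	TTTY17	AZFc	24310000	3	FALSE
TTTY17_02	TTTY17	AZFc	25060000	3	FALSE
TTTY17_03	TTTY17	AZFc	25810000	3	FALSE
TTTY3_01	TTTY3	AZFc	24455000	2	FALSE
TTTY3_02	TTTY3	AZFc	25305000	2	FALSE
REF_ACTB	ACTB	reference	NA	2	TRUE
REF_TBP	TBP	reference	NA	2	TRUE
REF_RPP30	RPP30	reference	NA	2	TRUE
REF_ZNF80	ZNF80	reference	NA	2	TRUE
REF_B2M	B2M	reference	NA	2	TRUE
REF_RPPH1	RPPH1	reference	NA	2	TRUE
REF_TERT	TERT	reference	NA	2	TRUE
REF_CFTR	CFTR	reference	NA	2	TRUE
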
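roi_id	label	hemisphere	tissue	networks
SFG_B	Superior frontal gyrus	B	GM	FPN
MTG_B	Middle temporal gyrus	B	GM	DMN
MCC_B	Mid cingulate cortex	B	GM	DMN;SMN
CAUD_B	Caudate nucleus	B	GM	LIM
CBM_B	Cerebellar cortex	B	GM	BSC
DACC_R	Dorsal anterior cingulate cortex	R	GM	SAL
DPCC_R	Dorsal posterior cingulate cortex	R	GM	DMN
PCUN_B	Precuneus	B	GM	DMN
MOFC_B	Medial orbitofrontal cortex	B	GM	DMN;LIM
HIPP_B	Hippocampus	B	GM	LIM
APAR_B	Anterior parietal cortex	B	GM	SMN
TOPER_B	Temporal operculum	B	GM	SAL
MFG_B	Middle frontal gyrus	B	GM	FPN
THAL_L	Thalamus	L	GM	LIM
RACC_WM_B	Rostral anterior cingulate white matter	B	WM	SAL;DMN
ISTC_B	Isthmus cingulate	B	GM	DMN;LIM
CUN_B	Cuneus	B	GM	SMN
IFG_L	Inferior frontal gyrus	L	GM	FPN
MFG_R	Middle frontal gyrus	R	GM	FPN
MTL_L	Medial temporal lobe	L	GM	LIM;DMN
PAR_L	Parietal cortex	L	GM	FPN
SFG_R	Superior frontal gyrus	R	GM	FPN
PRCG_R	Precentral gyrus	R	GM	SMN
AINS_R	Anterior insula	R	GM	SAL
ROLOP_R	Rolandic operculum	R	GM	SMN
STP_R	Superior temporal pole	R	GM	LIM
SLF_B	Superior longitudinal fasciculus	B	WM	FPN
FAT_B	Frontal aslant tract	B	WM	FPN
FPT_B	Frontopontine tract	B	WM	BSC
ARC_B	Arcuate fasciculus	B	WM	FPN
EXC_B	External capsule	B	WM	SAL
CST_B	Corticospinal tract	B	WM	SMN
THAL_B	Thalamus	B	GM	LIM
PRF_B	Pontine reticular formation	B	MIXED	BSC
CC_B	Corpus callosum	B	WM	CAL
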
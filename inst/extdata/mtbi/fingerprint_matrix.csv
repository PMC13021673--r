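roi_id,S01,S02,S03,S04,S05,S06,S07,S08,S09,S10
SFG_B,-1,0,0,-1,-1,0,0,0,0,0
MTG_B,-1,0,0,0,0,0,0,0,0,0
MCC_B,-1,0,0,0,0,0,0,0,0,0
CAUD_B,-1,0,0,0,0,0,0,0,0,0
CBM_B,-1,0,0,0,0,0,0,0,0,0
DACC_R,0,1,0,0,0,0,0,0,0,0
DPCC_R,0,1,0,0,0,0,0,0,0,0
PCUN_B,0,0,-1,0,-1,0,0,0,0,0
MOFC_B,0,0,-1,0,0,0,0,0,0,0
HIPP_B,0,0,-1,0,0,0,0,-1,0,-1
APAR_B,0,0,0,-1,0,0,0,0,0,0
TOPER_B,0,0,0,-1,0,0,0,0,0,0
MFG_B,0,0,0,-1,0,0,0,0,0,0
THAL_L,0,0,0,-1,0,0,0,0,0,0
RACC_WM_B,0,0,0,0,-1,0,0,0,0,0
ISTC_B,0,0,0,0,-1,0,0,0,0,0
CUN_B,0,0,0,0,-1,0,0,0,0,0
IFG_L,0,0,0,0,0,-1,0,0,0,0
MFG_R,0,0,0,0,0,-1,-1,0,0,0
MTL_L,0,0,0,0,0,-1,0,0,0,0
PAR_L,0,0,0,0,0,-1,0,0,0,0
SFG_R,0,0,0,0,0,0,-1,0,0,0
PRCG_R,0,0,0,0,0,0,-1,0,0,0
AINS_R,0,0,0,0,0,0,-1,0,0,0
ROLOP_R,0,0,0,0,0,0,-1,0,0,0
STP_R,0,0,0,0,0,0,-1,0,0,0
SLF_B,0,0,0,0,0,0,-1,0,0,0
FAT_B,0,0,0,0,0,0,-1,0,0,0
FPT_B,0,0,0,0,0,0,-1,0,0,0
ARC_B,0,0,0,0,0,0,-1,0,0,0
EXC_B,0,0,0,0,0,0,-1,0,0,0
CST_B,0,0,0,0,0,0,-1,0,0,0
THAL_B,0,0,0,0,0,0,0,-1,0,-1
PRF_B,0,0,0,0,0,0,0,0,-1,0
CC_B,0,0,0,0,0,0,0,0,0,-1
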
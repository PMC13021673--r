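roi_id	study_id	source_sentence_tag	confidence
SFG_B	S01	early_vbm_frontal_temporal_cingulate_subcortical_cerebellum	NARRATIVE
MTG_B	S01	early_vbm_frontal_temporal_cingulate_subcortical_cerebellum	NARRATIVE
MCC_B	S01	early_vbm_frontal_temporal_cingulate_subcortical_cerebellum	NARRATIVE
CAUD_B	S01	early_vbm_frontal_temporal_cingulate_subcortical_cerebellum	NARRATIVE
CBM_B	S01	early_vbm_frontal_temporal_cingulate_subcortical_cerebellum	NARRATIVE
DACC_R	S02	pth_increase_right_dorsal_anterior_posterior_cingulate	NARRATIVE
DPCC_R	S02	pth_increase_right_dorsal_anterior_posterior_cingulate	NARRATIVE
PCUN_B	S03	recurrent_precuneus_mofc_hippocampus	NARRATIVE
MOFC_B	S03	recurrent_precuneus_mofc_hippocampus	NARRATIVE
HIPP_B	S03	recurrent_precuneus_mofc_hippocampus	NARRATIVE
APAR_B	S04	pth_vbm_parietal_opercular_frontal_thalamus	NARRATIVE
TOPER_B	S04	pth_vbm_parietal_opercular_frontal_thalamus	NARRATIVE
SFG_B	S04	pth_vbm_parietal_opercular_frontal_thalamus	NARRATIVE
MFG_B	S04	pth_vbm_parietal_opercular_frontal_thalamus	NARRATIVE
THAL_L	S04	pth_vbm_parietal_opercular_frontal_thalamus	NARRATIVE
RACC_WM_B	S05	longitudinal_racc_wm_isthmus_precuneus_cuneus_frontal	NARRATIVE
ISTC_B	S05	longitudinal_racc_wm_isthmus_precuneus_cuneus_frontal	NARRATIVE
PCUN_B	S05	longitudinal_racc_wm_isthmus_precuneus_cuneus_frontal	NARRATIVE
CUN_B	S05	longitudinal_racc_wm_isthmus_precuneus_cuneus_frontal	NARRATIVE
SFG_B	S05	longitudinal_racc_wm_isthmus_precuneus_cuneus_frontal	NARRATIVE
IFG_L	S06	gm_proportion_frontal_mfg_mtl_parietal	NARRATIVE
MFG_R	S06	gm_proportion_frontal_mfg_mtl_parietal	NARRATIVE
MTL_L	S06	gm_proportion_frontal_mfg_mtl_parietal	NARRATIVE
PAR_L	S06	gm_proportion_frontal_mfg_mtl_parietal	NARRATIVE
SFG_R	S07	probability_year1_gm_frontal_insula_operculum_pole	NARRATIVE
MFG_R	S07	probability_year1_gm_frontal_insula_operculum_pole	NARRATIVE
PRCG_R	S07	probability_year1_gm_frontal_insula_operculum_pole	NARRATIVE
AINS_R	S07	probability_year1_gm_frontal_insula_operculum_pole	NARRATIVE
ROLOP_R	S07	probability_year1_gm_frontal_insula_operculum_pole	NARRATIVE
STP_R	S07	probability_year1_gm_frontal_insula_operculum_pole	NARRATIVE
SLF_B	S07	probability_year1_wm_tracts	NARRATIVE
FAT_B	S07	probability_year1_wm_tracts	NARRATIVE
FPT_B	S07	probability_year1_wm_tracts	NARRATIVE
ARC_B	S07	probability_year1_wm_tracts	NARRATIVE
EXC_B	S07	probability_year1_wm_tracts	NARRATIVE
CST_B	S07	probability_year1_wm_tracts	NARRATIVE
THAL_B	S08	longitudinal_thalamus_hippocampus_loss	NARRATIVE
HIPP_B	S08	longitudinal_thalamus_hippocampus_loss	NARRATIVE
PRF_B	S09	tbm_pontine_reticular_formation	NARRATIVE
THAL_B	S10	reconstructed_limbic_relay_volumetry	RECONSTRUCTED_LOW_CONFIDENCE
HIPP_B	S10	reconstructed_limbic_relay_volumetry	RECONSTRUCTED_LOW_CONFIDENCE
CC_B	S10	reconstructed_limbic_relay_volumetry	RECONSTRUCTED_LOW_CONFIDENCE
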
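study_id	citation	method	design	confidence
S01	Early voxel-based morphometry in mixed-severity traumatic brain injury	VBM	CROSS_SECTIONAL	NARRATIVE
S02	Cortical volumetry in mTBI with chronic post-traumatic headache	VOLUMETRY	CROSS_SECTIONAL	NARRATIVE
S03	Volumetry in recurrent mTBI with accelerated hippocampal atrophy	VOLUMETRY	CROSS_SECTIONAL	NARRATIVE
S04	Voxel-based morphometry in mTBI with and without post-traumatic headache	VBM	CROSS_SECTIONAL	NARRATIVE
S05	Longitudinal first-year cortical and pericingulate morphometry	VOLUMETRY	LONGITUDINAL	NARRATIVE
S06	Grey-matter proportion mapping stratified by post-concussive symptom severity	GM_PROB	CROSS_SECTIONAL	NARRATIVE
S07	One-year grey- and white-matter probability mapping	GM_PROB	LONGITUDINAL	NARRATIVE
S08	Longitudinal subcortical volumetry of thalamus and hippocampus	VOLUMETRY	LONGITUDINAL	NARRATIVE
S09	Tensor-based morphometry in chronic mTBI	TBM	CROSS_SECTIONAL	NARRATIVE
S10	Meta-analysis primary volumetric study; regional findings reconstructed (synthetic column)	VOLUMETRY	CROSS_SECTIONAL	RECONSTRUCTED_LOW_CONFIDENCE
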
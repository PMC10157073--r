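"feature","modality","roi","hemisphere"
"FA_cACC_left","FA","cACC_left","left"
"FA_cACC_right","FA","cACC_right","right"
"FA_dACC_left","FA","dACC_left","left"
"FA_dACC_right","FA","dACC_right","right"
"FA_rACC_left","FA","rACC_left","left"
"FA_rACC_right","FA","rACC_right","right"
"FA_sgACC_left","FA","sgACC_left","left"
"FA_sgACC_right","FA","sgACC_right","right"
"FA_pgACC_left","FA","pgACC_left","left"
"FA_pgACC_right","FA","pgACC_right","right"
"FA_amygdala_left","FA","amygdala_left","left"
"FA_amygdala_right","FA","amygdala_right","right"
"FA_CC1","FA","CC1","midline"
"FA_CC2","FA","CC2","midline"
"FA_CC3","FA","CC3","midline"
"FA_CC4","FA","CC4","midline"
"FA_CC5","FA","CC5","midline"
"MD_cACC_left","MD","cACC_left","left"
"MD_cACC_right","MD","cACC_right","right"
"MD_dACC_left","MD","dACC_left","left"
"MD_dACC_right","MD","dACC_right","right"
"MD_rACC_left","MD","rACC_left","left"
"MD_rACC_right","MD","rACC_right","right"
"MD_sgACC_left","MD","sgACC_left","left"
"MD_sgACC_right","MD","sgACC_right","right"
"MD_pgACC_left","MD","pgACC_left","left"
"MD_pgACC_right","MD","pgACC_right","right"
"MD_amygdala_left","MD","amygdala_left","left"
"MD_amygdala_right","MD","amygdala_right","right"
"MD_CC1","MD","CC1","midline"
"MD_CC2","MD","CC2","midline"
"MD_CC3","MD","CC3","midline"
"MD_CC4","MD","CC4","midline"
"MD_CC5","MD","CC5","midline"
"RD_cACC_left","RD","cACC_left","left"
"RD_cACC_right","RD","cACC_right","right"
"RD_dACC_left","RD","dACC_left","left"
"RD_dACC_right","RD","dACC_right","right"
"RD_rACC_left","RD","rACC_left","left"
"RD_rACC_right","RD","rACC_right","right"
"RD_sgACC_left","RD","sgACC_left","left"
"RD_sgACC_right","RD","sgACC_right","right"
"RD_pgACC_left","RD","pgACC_left","left"
"RD_pgACC_right","RD","pgACC_right","right"
"RD_amygdala_left","RD","amygdala_left","left"
"RD_amygdala_right","RD","amygdala_right","right"
"RD_CC1","RD","CC1","midline"
"RD_CC2","RD","CC2","midline"
"RD_CC3","RD","CC3","midline"
"RD_CC4","RD","CC4","midline"
"RD_CC5","RD","CC5","midline"
"AD_cACC_left","AD","cACC_left","left"
"AD_cACC_right","AD","cACC_right","right"
"AD_dACC_left","AD","dACC_left","left"
"AD_dACC_right","AD","dACC_right","right"
"AD_rACC_left","AD","rACC_left","left"
"AD_rACC_right","AD","rACC_right","right"
"AD_sgACC_left","AD","sgACC_left","left"
"AD_sgACC_right","AD","sgACC_right","right"
"AD_pgACC_left","AD","pgACC_left","left"
"AD_pgACC_right","AD","pgACC_right","right"
"AD_amygdala_left","AD","amygdala_left","left"
"AD_amygdala_right","AD","amygdala_right","right"
"AD_CC1","AD","CC1","midline"
"AD_CC2","AD","CC2","midline"
"AD_CC3","AD","CC3","midline"
"AD_CC4","AD","CC4","midline"
"AD_CC5","AD","CC5","midline"
"SC_amygdala_to_PFC_left","SC","amygdala_to_PFC_left","left"
"SC_PFC_to_amygdala_left","SC","PFC_to_amygdala_left","left"
"SC_amygdala_to_PFC_right","SC","amygdala_to_PFC_right","right"
"SC_PFC_to_amygdala_right","SC","PFC_to_amygdala_right","right"
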
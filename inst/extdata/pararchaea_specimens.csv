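specimen_id,state,carapace_width_um,clypeus_thickness_um,carapace_at_AME_um
CASENT9034335,closed,500.4,NA,NA
CASENT9034320,open,495.5,NA,NA
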
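gene,avg_logFC,adj_p,cell_type,block,probands
DDX60,0.38,0,all_pbmc,candidate_genes,P3
DDX60,0.48,3.88e-209,mono_cdc_pdc,candidate_genes,P3
DDX60,0.38,1.33e-255,t_cells,candidate_genes,P3
DDX60,0.33,1.53e-81,b_cells,candidate_genes,P3
TMEM154,0.32,1.41e-150,all_pbmc,candidate_genes,P3
TMEM154,0.33,7.68e-25,mono_cdc_pdc,candidate_genes,P3
TMEM154,0.40,2.13e-61,b_cells,candidate_genes,P3
RASSF3,0.33,4.38e-38,mono_cdc_pdc,candidate_genes,P3
LY9,-0.33,2.22e-09,b_cells,candidate_variants,P13;P23
IFIH1,0.40,5.20e-83,mono_cdc_pdc,candidate_variants,P11;P15;P20
DOCK8,0.29,2.04e-142,all_pbmc,candidate_variants,P16;P18;P23
DOCK8,0.55,3.68e-93,mono_cdc_pdc,candidate_variants,P16;P18;P23
DCLRE1C,0.28,1.70e-29,b_cells,candidate_variants,P9
LYST,0.55,6.51e-83,mono_cdc_pdc,candidate_variants,P4;P13
ISG15,0.62,1.10e-40,all_pbmc,background,.
MX1,0.58,4.00e-55,mono_cdc_pdc,background,.
IFI6,0.51,2.30e-33,t_cells,background,.
OAS1,0.44,8.70e-29,mono_cdc_pdc,background,.
STAT1,0.41,5.60e-61,all_pbmc,background,.
IRF7,0.39,3.10e-22,mono_cdc_pdc,background,.
S100A8,0.71,9.90e-88,mono_cdc_pdc,background,.
CD74,-0.28,6.40e-19,b_cells,background,.
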
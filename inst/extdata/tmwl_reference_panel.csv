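membrane,formulation,class,replicate,tmwl
nuclepore,control,control,1,80.8
sublingual_mucosa,control,control,1,72.4
nuclepore,F01_tea_tree_mouthwash,hydrophobic,1,71.3
nuclepore,F02_semisolid_anhydrous_absorption_base,hydrophobic,1,15.98
nuclepore,F03_lipophilic_base_MI,hydrophobic,1,2.6
nuclepore,F04_lipophilic_base_TGCM,hydrophobic,1,3.6
nuclepore,F05_fluid_anhydrous_absorption_base,hydrophobic,1,22.5
nuclepore,F06_sodium_cmc_gel_4pct,hydrophilic,1,64.6
nuclepore,F07_sodium_hyaluronate_gel_2pct,hydrophilic,1,75.4
nuclepore,F08_chitosan_gel_2pct,hydrophilic,1,75.2
nuclepore,F09_alginate_gel_4pct,hydrophilic,1,74.5
nuclepore,F10_gel_plx_cbp,hydrophilic,1,74.8
nuclepore,F11_pc_10pct,liposomal,1,57.8
nuclepore,F12_hpc_10pct,liposomal,1,68.0
nuclepore,F13_cer3_1pct,liposomal,1,59.3
nuclepore,F14_cer3_10pct,liposomal,1,57.2
nuclepore,F15_cer3cer6_1pct,liposomal,1,49.2
nuclepore,F16_cer3cer6_10pct,liposomal,1,50.4
sublingual_mucosa,F01_tea_tree_mouthwash,hydrophobic,1,58.5
sublingual_mucosa,F02_semisolid_anhydrous_absorption_base,hydrophobic,1,23.6
sublingual_mucosa,F03_lipophilic_base_MI,hydrophobic,1,6.5
sublingual_mucosa,F04_lipophilic_base_TGCM,hydrophobic,1,3.0
sublingual_mucosa,F05_fluid_anhydrous_absorption_base,hydrophobic,1,34.2
sublingual_mucosa,F06_sodium_cmc_gel_4pct,hydrophilic,1,53.8
sublingual_mucosa,F07_sodium_hyaluronate_gel_2pct,hydrophilic,1,59.3
sublingual_mucosa,F08_chitosan_gel_2pct,hydrophilic,1,63.0
sublingual_mucosa,F09_alginate_gel_4pct,hydrophilic,1,62.9
sublingual_mucosa,F10_gel_plx_cbp,hydrophilic,1,57.0
sublingual_mucosa,F11_pc_10pct,liposomal,1,66.1
sublingual_mucosa,F12_hpc_10pct,liposomal,1,63.7
sublingual_mucosa,F13_cer3_1pct,liposomal,1,65.6
sublingual_mucosa,F14_cer3_10pct,liposomal,1,60.8
sublingual_mucosa,F15_cer3cer6_1pct,liposomal,1,47.2
sublingual_mucosa,F16_cer3cer6_10pct,liposomal,1,45.1
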
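name,abbrev,log_kow,mw,lod,loq
caffeine,CAF,-0.1,194.2,0.82,2.49
ketorolac_tromethamine,KET,2.3,376.4,0.10,0.28
dexamethasone,DEX,1.8,392.5,0.23,0.70
ivermectin,IVE,5.8,875.1,0.55,1.66
fungitrol,FUN,2.4,281.1,1.09,3.31
propiconazole,PRO,3.5,342.2,0.37,1.11
permethrin,PER,6.5,391.3,0.49,1.49
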
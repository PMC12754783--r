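name,sequence,strand_count,ligand_name,ligand_mass
222T,TGGGTTGGGTTGGGTTGGGT,1,QQPQ,1000
5YEY,GGGTTAGGGTTAGGGTTTGGG,1,QQPQ,1000
TG4T,TGGGGT,4,,
T6,TTTTTT,1,,
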
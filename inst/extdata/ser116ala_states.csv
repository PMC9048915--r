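"taxon","state"
"Dryas_iulia",0
"Eueides_isabella",0
"Heliconius_erato",0
"Heliconius_melpomene",0
"Heliconius_hecale",0
"Heliconius_ismenius",1
"Heliconius_numata",1
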
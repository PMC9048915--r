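(Dryas_iulia:0.12,(Eueides_isabella:0.09,(Heliconius_erato:0.065,(Heliconius_melpomene:0.05,((Heliconius_numata:0.02,Heliconius_ismenius:0.02):0.015,Heliconius_hecale:0.03):0.02):0.018):0.03):0.02);
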
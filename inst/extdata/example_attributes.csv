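taxon_id,family,ffg,tolerance,overwinters
Chironomus,Chironomidae,collector,8,TRUE
Gyraulus,Planorbidae,grazer,6,TRUE
Planorbis,Planorbidae,grazer,6.5,TRUE
Enallagma,Coenagrionidae,predator,8,TRUE
Caenis,Caenidae,collector,7,FALSE
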
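site_id,taxon_id,abundance,year,ecoregion,vegetation
w101,Chironomus,23,2011,LHW,bulrush
w101,Gyraulus,4,2011,LHW,bulrush
w101,Enallagma,2,2011,LHW,bulrush
w102,Chironomus,11,2011,LHW,bulrush
w102,Planorbis,7,2011,LHW,bulrush
w102,Caenis,3,2011,LHW,bulrush
w103,Gyraulus,9,2011,LHW,bulrush
w103,Enallagma,5,2011,LHW,bulrush
w103,Caenis,12,2011,LHW,bulrush
w104,Chironomus,2,2011,LHW,bulrush
w104,Planorbis,1,2011,LHW,bulrush
w104,Gyraulus,6,2011,LHW,bulrush
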
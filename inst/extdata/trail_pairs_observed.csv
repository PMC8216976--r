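association_type,species,tide_phase,combination,count,declared_N
trail_following,E_malaccana,rising,FM,68,126
trail_following,E_malaccana,rising,MM,26,126
trail_following,E_malaccana,rising,MF,12,126
trail_following,E_malaccana,rising,FF,20,126
trail_following,E_malaccana,falling,FM,38,120
trail_following,E_malaccana,falling,MM,29,120
trail_following,E_malaccana,falling,MF,23,120
trail_following,E_malaccana,falling,FF,30,120
trail_following,E_radiata,rising,FM,61,120
trail_following,E_radiata,rising,MM,15,120
trail_following,E_radiata,rising,MF,14,120
trail_following,E_radiata,rising,FF,30,120
trail_following,E_radiata,falling,FM,32,120
trail_following,E_radiata,falling,MM,25,120
trail_following,E_radiata,falling,MF,30,120
trail_following,E_radiata,falling,FF,NA,120
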
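association_type,species,tide_phase,combination,count,declared_N
tower,E_malaccana,before_rising,FM,31,41
tower,E_malaccana,before_rising,MM,2,41
tower,E_malaccana,before_rising,MF,3,41
tower,E_malaccana,before_rising,FF,5,41
tower,E_malaccana,after_falling,FM,23,64
tower,E_malaccana,after_falling,MM,17,64
tower,E_malaccana,after_falling,MF,7,64
tower,E_malaccana,after_falling,FF,17,64
tower,E_radiata,before_rising,FM,36,40
tower,E_radiata,before_rising,MM,2,40
tower,E_radiata,before_rising,MF,0,40
tower,E_radiata,before_rising,FF,2,40
tower,E_radiata,after_falling,FM,25,43
tower,E_radiata,after_falling,MM,10,43
tower,E_radiata,after_falling,MF,4,43
tower,E_radiata,after_falling,FF,4,43
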
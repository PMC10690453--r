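species,logK_apparent,ph,temperature_C
CaEGTA,6.91,7.2,37
MgEGTA,2.38,7.2,37
CaATP,3.79,7.2,37
MgATP,4.10,7.2,37
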
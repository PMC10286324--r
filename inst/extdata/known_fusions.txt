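SLC45A3::ELK4
TMPRSS2::ERG
TMPRSS2::ETV4
TTC6::MIPOL1
SLC45A3::ERG
ERG::TMPRSS2
PMEPA1::ETV4
SLC45A3::ETV1
IQSEC1::SCCPDH
GPATCH8::PYY
PDZRN3::EIF4E3
TMPRSS2::ETV1
SLC45A3::ETV4
TMPRSS2::ETV5
NDRG1::ERG
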
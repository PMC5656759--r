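name	motif6_variant	triad_variant
SINV-2	GDD	GxSG
M. pharaonis TSA LA858223.1	GDD	GxSG
LniV-1	GDD	GxSG
L. neglectus TSA	GDD	GxSG
L. humile TSA	GDD	GxSG
M. pharaonis TSA LA866448.1	GDD	GxSG
Shuangao insect virus 8	GDD	GxSG
SINV-4	GDD	GxSG
MsaV-1	GDD	GxSG
LneV-1	GDD	GxSG
F. exsecta TSA	GDD	GxSG
Hubei picorna-like virus 81 KX884540.1	GDD	GxSG
Hubei picorna-like virus 81 KX883940.1	GDD	GxSG
Ch. riparius TSA	ADD	GxSG
Hubei picorna-like virus 82	ADD	GxSG
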
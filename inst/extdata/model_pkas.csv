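residue,type,pka
CTR,acid,3.2
ASP,acid,4.0
GLU,acid,4.4
HIS,base,6.3
NTR,base,8.0
CYS,acid,8.3
TYR,acid,9.6
LYS,base,10.4
ARG,base,12.0
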
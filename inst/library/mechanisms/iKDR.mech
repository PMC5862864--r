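% iKDR: fast delayed-rectifier potassium current for interneuron-style spiking (Wang & Buzsaki 1996)
% kind: intrinsic
gKDR = 9
EKDR = -90
aN(V) = 0.05*(V+34)/(1-exp(-(V+34)/10))
bN(V) = 0.625*exp(-(V+44)/80)
IKDR(V,nKDR) = -gKDR*nKDR^4*(V-EKDR)
dnKDR/dt = aN(V)*(1-nKDR) - bN(V)*nKDR
nKDR(0) = 0.09
@current += IKDR
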
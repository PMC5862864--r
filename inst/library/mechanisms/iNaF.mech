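% iNaF: fast spike-generating sodium current with instantaneous activation (Wang & Buzsaki 1996)
% kind: intrinsic
gNaF = 35
ENaF = 55
aM(V) = 0.1*(V+35)/(1-exp(-(V+35)/10))
bM(V) = 4*exp(-(V+60)/18)
minf(V) = aM(V)/(aM(V)+bM(V))
aH(V) = 0.35*exp(-(V+58)/20)
bH(V) = 5/(1+exp(-(V+28)/10))
INaF(V,hNaF) = -gNaF*minf(V)^3*hNaF*(V-ENaF)
dhNaF/dt = aH(V)*(1-hNaF) - bH(V)*hNaF
hNaF(0) = 0.78
@current += INaF
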
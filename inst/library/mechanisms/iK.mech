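% iK: delayed-rectifier potassium current, squid-axon kinetics (Hodgkin & Huxley 1952)
% kind: intrinsic
gK = 36
EK = -77
aN(V) = 0.01*(V+55)/(1-exp(-(V+55)/10))
bN(V) = 0.125*exp(-(V+65)/80)
IK(V,n) = -gK*n^4*(V-EK)
dn/dt = aN(V)*(1-n) - bN(V)*n
n(0) = 0.3177
@current += IK
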
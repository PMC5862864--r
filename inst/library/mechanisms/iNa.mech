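% iNa: fast transient sodium current, squid-axon kinetics (Hodgkin & Huxley 1952)
% kind: intrinsic
gNa = 120
ENa = 50
aM(V) = 0.1*(V+40)/(1-exp(-(V+40)/10))
bM(V) = 4*exp(-(V+65)/18)
aH(V) = 0.07*exp(-(V+65)/20)
bH(V) = 1/(1+exp(-(V+35)/10))
INa(V,m,h) = -gNa*m^3*h*(V-ENa)
dm/dt = aM(V)*(1-m) - bM(V)*m
m(0) = 0.0529
dh/dt = aH(V)*(1-h) - bH(V)*h
h(0) = 0.5961
@current += INa
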
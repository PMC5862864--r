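% iM: slow M-type potassium current, simplified high-threshold form; builds up across spikes and paces burst termination (cf. Traub et al. 2003)
% kind: intrinsic
gM = 4
EM = -90
winf(V) = 1/(1+exp(-(V+15)/5))
tauW(V) = 90 + 0*V
IM(V,wM) = -gM*wM*(V-EM)
dwM/dt = (winf(V)-wM)/tauW(V)
wM(0) = 0
@current += IM
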
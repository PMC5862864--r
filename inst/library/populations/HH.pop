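% HH: Hodgkin-Huxley neuron with iNa and iK currents plus ohmic leak (Hodgkin & Huxley 1952)
% kind: population
Cm = 1
gL = 0.3
EL = -54.4
Iapp = 0
dV/dt = (Iapp - gL*(V-EL) + @current)/Cm
V(0) = -65
mechanism_list: iNa, iK
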
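% LIF: leaky integrate-and-fire neuron with parameterized refractory period
% kind: population
Cm = 1
gL = 0.1
EL = -65
Vth = -40
Vreset = -70
tref = 2
Iapp = 0
dV/dt = ((Iapp - gL*(V-EL) + @current)/Cm)*(t - tlast > tref)
V(0) = -65
dtlast/dt = 0
tlast(0) = -1e9
if(V >= Vth)(V = Vreset; tlast = t)
monitor V.spikes(-45)
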
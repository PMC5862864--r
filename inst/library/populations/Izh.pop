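% Izh: Izhikevich neuron, regular-spiking parameterization (Izhikevich 2003)
% kind: population
a = 0.03
b = -2
c = -50
d = 100
vr = -60
vpeak = 35
Iapp = 0
I(t) = Iapp
dv/dt = .01*(.7*(v-vr)*(v+40) - u + I(t))
v(0) = vr
du/dt = a*(b*(v-vr) - u)
u(0) = 0
if(v > vpeak)(v = c; u = u + d)
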
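% iAMPA: AMPA-type excitatory synapse, first-order gating with sigmoid presynaptic threshold (first-order kinetic synapse, Destexhe et al. 1994)
% kind: connection
gAMPA = 0.1
EAMPA = 0
tauD = 2
rate = 5
fpre(x) = 1/(1+exp(-x/2))
ds/dt = rate*fpre(V_pre)*(1-s) - s/tauD
s(0) = 0
IAMPA(V_post,s) = -gAMPA*matmul(netcon,s)*(V_post-EAMPA)/Npre
@current += IAMPA
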
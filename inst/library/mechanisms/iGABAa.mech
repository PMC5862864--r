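% iGABAa: GABA-A-type inhibitory synapse, first-order gating with sigmoid presynaptic threshold (first-order kinetic synapse, Destexhe et al. 1994)
% kind: connection
gGABAa = 0.1
EGABAa = -80
tauD = 10
rate = 2
fpre(x) = 1/(1+exp(-x/2))
ds/dt = rate*fpre(V_pre)*(1-s) - s/tauD
s(0) = 0
IGABAa(V_post,s) = -gGABAa*matmul(netcon,s)*(V_post-EGABAa)/Npre
@current += IGABAa
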
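% iNaP: persistent (non-inactivating) sodium current; subthreshold window current supporting plateau depolarizations (Durstewitz et al. 2000)
% kind: intrinsic
gNaP = 0.5
ENaP = 55
pinf(V) = 1/(1+exp(-(V+50)/4))
INaP(V) = -gNaP*pinf(V)*(V-ENaP)
@current += INaP
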
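% iCOM: ohmic axial current joining two compartments of one neuron
% kind: connection
gCOM = 0.2
degCOM = matmul(netcon, ones(Npre))
ICOM(V_post) = -gCOM*(degCOM*V_post - matmul(netcon,V_pre))
@current += ICOM
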
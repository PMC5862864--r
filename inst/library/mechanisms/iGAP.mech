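% iGAP: ohmic gap junction (electrical coupling)
% kind: connection
gGAP = 0.1
degGAP = matmul(netcon, ones(Npre))
IGAP(V_post) = -gGAP*(degGAP*V_post - matmul(netcon,V_pre))/Npre
@current += IGAP
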
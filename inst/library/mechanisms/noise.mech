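% noise: additive Gaussian current noise; per-step increment scales with sqrt(dt)
% kind: input
noise_amp = 0
Inoise(t) = noise_amp*sqrt(dt)*randn(1,Npop)
@current += Inoise
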
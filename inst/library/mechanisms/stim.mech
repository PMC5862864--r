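% stim: tonic current step between stim_onset and stim_offset (ms)
% kind: input
stim_amp = 0
stim_onset = 0
stim_offset = 1e9
Istim(t) = stim_amp*(t>=stim_onset)*(t<stim_offset)
@current += Istim
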
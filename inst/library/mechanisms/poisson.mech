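% poisson: nonhomogeneous Poisson input by per-step thinning; poisson_rate in events/s per cell
% kind: input
poisson_rate = 0
poisson_amp = 1
Ipoisson(t) = poisson_amp*(rand(1,Npop) < poisson_rate*dt/1000)/dt
@current += Ipoisson
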
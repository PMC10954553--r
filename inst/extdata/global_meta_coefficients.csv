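model,term,beta,ci_low,ci_high,p
average,(Intercept),0.004087,0.003072,0.005102,2.9e-15
average,tLatitude,-0.000044,-0.000107,0.000019,0.17
abundance,(Intercept),0.007527,0.005870,0.009183,5.3e-19
abundance,tLatitude,-0.000172,-0.000315,-0.000030,0.018
abundance,tAbundance,-0.000990,-0.001353,-0.000626,9.5e-8
abundance,tLatitude:tAbundance,0.000035,0.000006,0.000064,0.017
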
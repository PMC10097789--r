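constant,value,unit
E0_MPa,22500,MPa
nu0,0.3,-
G0_MPa,8650.0,MPa
k,1.9,-
l,0.99,-
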
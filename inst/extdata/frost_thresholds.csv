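threshold,description,strain_lo_ustrain,strain_hi_ustrain,stress_lo_MPa,stress_hi_MPa,sed_lo_MPa,sed_hi_MPa
MESr,threshold range for disuse-mode remodeling,50,100,1,2,2.8e-5,11.25e-5
MESm,threshold for bone modeling,1000,1500,20,NA,0.01125,0.02531
MESp,operational microdamage threshold,3000,NA,60,NA,0.10125,NA
Fx,ultimate strength and fracture,25000,NA,120,NA,1.5,NA
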
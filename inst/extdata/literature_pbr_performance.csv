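design,abs_cos_alpha,tke_cm2_s2,f_hz,phi_pct,source
Tangent double-tube PBR,0.69,80,1.8,47.8,this framework's reference configuration
Concentric double-tube PBR,0.5,54,1.01,35.1,this framework's reference configuration
Serial lantern-shaped draft tube PBR,NA,26.6,0.476,32.9,Ye et al.
Tubular PBR with internal static mixers,NA,23,NA,NA,Azizi et al.
Tubular PBR with Kenics mixer units,NA,NA,0.615,NA,Qin and Wu
Tubular PBR with spiral ribs,NA,NA,1.2,NA,Lei et al.
Twisted tubular PBR,NA,NA,2.45,NA,Gomez-Perez et al.
Draft-tube airlift PBR,NA,53,0.7,NA,Xu et al.
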
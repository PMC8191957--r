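species,group,B,W,U,N,L,lam,h,n_w,f,ell,d,kappa,notes,refs
Halobacterium salinarum,archaea,2.6 ± 0.5 (1.6⋆ − 10),0.43 ± 0.07 (max1),3.3 ± 0.9 (max10),,4.3 ± 1,2.1 ± 0.2,0.22 ± 0.03,,23 ± 5,,,,archaellum,compilation
Pseudomonas fluorescens,bacteria,3.1 ± 0.8,0.9 ± 0.1,77.6 (max 102),1.5 ± 1.1,8.4 ± 1.3,1.76,0.39,2.5,,,,,run speed; SBW25,compilation
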
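species,group,B,W,U,N,L,lam,h,n_w,f,ell,d,kappa,notes,refs
Tetrahymena pyriformis,ciliate,70 (55.7 − 89.77⋆),27.5⋆ (20 − 45),480 (451.2 − 500),500,,,,,20,(7 − 14.35⋆),(2.84 − 6.16)⋆,0.2,excluding compound cilia,compilation
Paramecium caudatum,ciliate,242 (140 − 311),48 (35 − 70),1476.5 (478.7 − 4500),,,,,,31.4 ± 8.3,12,,(0.5 − 11.1),dexioplectic metachrony,compilation
Paramecium spp.,ciliate,210 (150 − 250),,1000 (750 − 1200),5000,,,,,32,(10 − 12),,(0.25 − 0.5),no width reported (skips model inversions),compilation
Paramecium multimicronucleatum,ciliate,251 ± 18 (168 − 280),62 (42 − 77),2843 (2173 − 4166),,,,,,32.5 ± 2.5,14.2,(2.56 − 4.2),,antiplectic metachronism,compilation
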
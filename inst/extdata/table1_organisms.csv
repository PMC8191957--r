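species,group,B,W,U,N,L,lam,h,n_w,f,ell,d,kappa,notes,refs
Escherichia coli,bacteria,2.5 ± 0.6,0.88 ± 0.09,24.1 ± 10 (14.2 − 60),6,8.3 ± 2.0,2.366 ± 0.121,0.38⋆,,131 ± 31,8.3 ± 2.0,,,peritrichous; wild-type AW405,compilation
Halobacterium salinarum,archaea,2.6 ± 0.5 (1.6⋆ − 10),0.43 ± 0.07 (max1),3.3 ± 0.9 (max10),,4.3 ± 1,2.1 ± 0.2,0.22 ± 0.03,,23 ± 5,4.3 ± 1,,,mono- or bipolar tuft,compilation
Giardia lamblia,flagellate,(10.4 − 12.1)⋆,(7.3 − 8.9)⋆,(12 − 40),8,(10.6 − 12.5)⋆,(2.73 − 5.5),(0.2 − 0.31),2,13,(10.6 − 12.5)⋆,,,four flagellar pairs,compilation
Bull spermatozoon,spermatozoon,8.87 (6.77 − 10.2),4.74 (4.2 − 5.4),97 ± 6 (40 − 160),1,(44.2 − 63.83),(30.5⋆ − 40),8 (7.1⋆ − 11),1,20.57 ± 3.4,(44.2 − 63.83),,,3D helical or complex beat,compilation
Paramecium caudatum,ciliate,242 (140 − 311),48 (35 − 70),1476.5 (478.7 − 4500),,,,,,31.4 ± 8.3,12,,(0.5 − 11.1),dexioplectic metachrony,compilation
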
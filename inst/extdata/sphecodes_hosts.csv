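species,spec_I,spec_II,spec_III,LS,LO,H,S,A,C,P,M,n_genera,sporadic_extra,eco_similar
S. albilabris,S,G,G,0,0,1,0,0,1,0,1,3,TRUE,FALSE
S. alternatus,S,S,S,0,0,1,0,0,0,0,0,1,FALSE,TRUE
S. autumnalis,S,S,S,0,0,0,0,0,0,1,0,1,FALSE,TRUE
S. clematidis,?,?,?,0,0,0,0,0,0,0,0,0,FALSE,FALSE
S. confertus,S,S,S,0,0,0,0,1,0,0,0,1,FALSE,TRUE
S. crassus,S,G,G,0,1,0,0,0,0,0,0,1,FALSE,FALSE
S. cristatus,S,S,G,0,1,0,1,0,0,0,0,2,TRUE,TRUE
S. croaticus,S,S,S,0,1,0,0,0,0,0,0,1,FALSE,TRUE
S. dusmeti,?,?,?,0,0,0,0,0,0,0,0,0,FALSE,FALSE
S. ephippius,G,G,G,1,1,1,1,1,0,0,0,3,FALSE,FALSE
S. ferruginatus,S,S,S,0,1,0,0,0,0,0,0,1,FALSE,TRUE
S. geoffrellus,S,G,G,0,1,0,0,0,0,0,0,1,FALSE,FALSE
S. gibbus,S,G,G,0,1,1,0,0,0,0,0,2,TRUE,FALSE
S. hyalinatus,S,S,S,0,1,0,0,0,0,0,0,1,FALSE,TRUE
S. longuloides,S,S,S,0,1,0,0,0,0,0,0,1,FALSE,TRUE
S. longulus,S,S,S,0,1,0,0,0,0,0,0,1,FALSE,TRUE
S. majalis,S,S,S,1,0,0,0,0,0,0,0,1,FALSE,TRUE
S. marginatus,S,S,S,0,1,0,0,0,0,0,0,1,FALSE,TRUE
S. miniatus,S,S,S,0,1,0,0,0,0,0,0,1,FALSE,TRUE
S. monilicornis,G,G,G,1,1,1,1,1,0,0,0,3,FALSE,FALSE
S. niger,S,S,S,0,1,0,0,0,0,0,0,1,FALSE,TRUE
S. nomioidis,?,?,?,0,0,0,0,0,0,0,0,0,FALSE,FALSE
S. olivieri,S,S,S,1,1,0,0,0,0,0,0,1,FALSE,TRUE
S. pellucidus,S,G,G,1,0,0,0,0,1,0,0,2,TRUE,FALSE
S. pinguiculus,S,S,S,0,0,0,1,0,0,0,0,1,FALSE,TRUE
S. pseudofasciatus,?,?,?,0,0,0,0,0,0,0,0,0,FALSE,FALSE
S. puncticeps,S,S,S,0,1,0,0,0,0,0,0,1,FALSE,TRUE
S. ranunculi,?,?,?,0,0,0,0,0,0,0,0,0,FALSE,FALSE
S. reticulatus,S,G,G,1,0,0,0,0,1,0,0,2,TRUE,FALSE
S. rubicundus,S,S,S,0,0,0,0,1,0,0,0,1,FALSE,TRUE
S. ruficrus,S,S,S,0,0,0,0,1,0,0,0,1,FALSE,TRUE
S. rufiventris,S,S,S,0,0,1,0,0,0,0,0,1,FALSE,TRUE
S. scabricollis,S,S,S,1,0,0,0,0,0,0,0,1,FALSE,TRUE
S. schenckii,S,S,S,1,0,0,0,0,0,0,0,1,FALSE,TRUE
S. sp. 17,?,?,?,0,0,0,0,0,0,0,0,0,FALSE,FALSE
S. spinulosus,S,S,S,1,0,0,0,0,0,0,0,1,FALSE,TRUE
S. zangheri,?,?,?,0,0,0,0,0,0,0,0,0,FALSE,FALSE
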
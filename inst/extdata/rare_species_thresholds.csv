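species,pollutant,sensitivity,region,functional_group,occurrences,peak_dep,t20,t50,t90
Nephroma occultum,N,oligotroph,West,cyano_large,29,2.9,4,4.9,6
Pannaria conoplea,N,oligotroph,East,cyano_small_med,14,4.2,5.7,7,8.8
Collema subflaccidum,N,mesotroph,West,cyano_small_med,9,4.6,5.8,6.5,12.3
Ramalina sinensis,N,mesotroph,East,forage_shrubby,18,7.0,8.2,9.2,11
Heterodermia leucomela,N,eutroph,West,matrix_med_large,36,8.2,9.9,11,12.2
Coccocarpia palmicola,N,eutroph,East,matrix_small,13,9.9,11.6,14,17
Scytinium cellulosum,S,sensitive,West,cyano_small_med,13,1.6,2.5,3.2,8.8
Usnea longissima,S,sensitive,East,forage_pendant,18,2.7,4.7,5.8,7.6
Ramalina obtusata,S,intermediate,West,forage_shrubby,9,5.3,6.8,7.7,8.7
Pseudocyphellaria crocata,S,intermediate,East,cyano_large,15,4.2,5.4,6.5,8.2
Cladonia cenotea,S,tolerant,West,matrix_small,29,8.7,,,
Heterodermia granulifera,S,tolerant,East,matrix_med_large,15,13.8,16,18.8,23.9
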
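genus,functional_group,form_dependent
Anomolobaria,cyano_large,FALSE
Dendriscosticta,cyano_large,FALSE
Lobaria,cyano_large,FALSE
Nephroma,cyano_large,FALSE
Peltigera,cyano_large,FALSE
Pseudocyphellaria,cyano_large,FALSE
Sticta,cyano_large,FALSE
Collema,cyano_small_med,FALSE
Dendriscocaulon,cyano_small_med,FALSE
Enchylium,cyano_small_med,FALSE
Erioderma,cyano_small_med,FALSE
Fuscopannaria,cyano_small_med,FALSE
Lathagrium,cyano_small_med,FALSE
Leioderma,cyano_small_med,FALSE
Leptogium,cyano_small_med,FALSE
Leptochidium,cyano_small_med,FALSE
Pannaria,cyano_small_med,FALSE
Scytinium,cyano_small_med,FALSE
Vahliella,cyano_small_med,FALSE
Alectoria,forage_pendant,FALSE
Bryocaulon,forage_pendant,FALSE
Bryoria,forage_pendant,FALSE
Nodobryoria,forage_pendant,FALSE
Ramalina,forage_pendant,TRUE
Usnea,forage_pendant,TRUE
Bunodophorun,forage_shrubby,FALSE
Evernia,forage_shrubby,FALSE
Letharia,forage_shrubby,FALSE
Pseudevernia,forage_shrubby,FALSE
Sphaerophorus,forage_shrubby,FALSE
Teleoschistes,forage_shrubby,FALSE
Ahtiana,matrix_med_large,FALSE
Canoparmelia,matrix_med_large,FALSE
Cetrelia,matrix_med_large,FALSE
Crespoa,matrix_med_large,FALSE
Esslingeriana,matrix_med_large,FALSE
Flavoparmelia,matrix_med_large,FALSE
Flavopunctelia,matrix_med_large,FALSE
Heterodermia,matrix_med_large,FALSE
Hypogymnia,matrix_med_large,FALSE
Hypotrachyna,matrix_med_large,FALSE
Imshaugia,matrix_med_large,FALSE
Melanelixia,matrix_med_large,FALSE
Melanohalea,matrix_med_large,FALSE
Menegazzia,matrix_med_large,FALSE
Montanelia,matrix_med_large,FALSE
Myelochroa,matrix_med_large,FALSE
Niebla,matrix_med_large,FALSE
Parmelia,matrix_med_large,FALSE
Parmelina,matrix_med_large,FALSE
Parmotrema,matrix_med_large,FALSE
Physcia,matrix_med_large,FALSE
Physconia,matrix_med_large,FALSE
Platismatia,matrix_med_large,FALSE
Punctelia,matrix_med_large,FALSE
Teloschistes,matrix_med_large,FALSE
Tuckermanella,matrix_med_large,FALSE
Tuckermannopsis,matrix_med_large,FALSE
Usnocetraria,matrix_med_large,FALSE
Vulpicida,matrix_med_large,FALSE
Anaptychia,matrix_small,FALSE
Bulbothrix,matrix_small,FALSE
Candelaria,matrix_small,FALSE
Cavernularia,matrix_small,FALSE
Cladonia,matrix_small,FALSE
Coccocarpia,matrix_small,FALSE
Hyperphyscia,matrix_small,FALSE
Kaernefeltia,matrix_small,FALSE
Loxosporopsis,matrix_small,FALSE
Parmeliella,matrix_small,FALSE
Parmeliopsis,matrix_small,FALSE
Phaeophyscia,matrix_small,FALSE
Physciella,matrix_small,FALSE
Placidium,matrix_small,FALSE
Polycaulon,matrix_small,FALSE
Polychidium,matrix_small,FALSE
Pyxine,matrix_small,FALSE
Rusavskia,matrix_small,FALSE
Xanthomendoza,matrix_small,FALSE
Xanthoria,matrix_small,FALSE
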
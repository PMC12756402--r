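((YEAST,SCHPO)Fungi,(CAPOW,((MONBR,SALS5)Choanozoa,(AMPQE,(TRIAD,((NEMVE,HYDMA)Cnidaria,(((CAEEL,(DROME,IXOSC)Arthropoda)Ecdysozoa,(HELRO,LOTGI)Lophotrochozoa)Protostomia,((STRPU,SACKO)Ambulacraria,(BRAFL,(CIOIN,(PETMA,(TETNI,(XENTR,(HUMAN,(ANOCA,CHICK)Sauria)Amniota)Tetrapoda)Euteleostomi)Vertebrata)Olfactores)Chordata)Deuterostomia)Bilateria)Planulozoa)ParaHoxozoa)Metazoa)Holozoa)Filozoa)Opisthokonta;
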
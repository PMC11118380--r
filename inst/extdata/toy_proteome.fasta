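>SYNBRD4 synthetic BRD4-like protein (constructed stand-in)
MSTEGAKLVDRINELAGQFVDKSTRPELAMTMSTEGAKLVDRINELAGQFVDKSTRPELA
MTMSTEGAKLVDRINELAGQFVDKSTRPELAMTMSTEGAKLVDRINELAGQFVDKSTRPE
LAMTMSTEGAKLVDRINELAGQFVDKSTRPELAMTMSTEGAKLVDRINELAGQFVDKSTR
PELAMTMSTEGAKLVDRINELAGQFVDKSTRPELAMTMSTEGAKLVDRINELAGQFVDKS
TRPELAMTMSTEGAKLVDRINELAGQFVDKSTRPELAMTMSTEGAKLVDRINELAGQFVD
KSTRPELAMTMSTEGAKLVDRINELAGQFVDKSTRPELAMTMSTEGAKLVDRINELAGQF
VDKSTRPELAMTMSTEGAKLVDRINELAGQFVDKSTRPELAMTMSTEGAKLVDRINELAG
QFVDKSTRPELAMTMSTEGAKLVDRINELAGQFVDKSTRPELAMTMSTEGAKLVDRINEL
AGQFVDKSTRPELAMTMSTEGAKLVDRINELAGQFVDKSTRPELAMTMSTEGAKLVDRIN
ELAGQFVDKSTRPELAMTMSTEGAKLVDRINELAGQFVDKSTRPELAMTMSTEGAKLVDR
INELAGQFVDKSTRPELAMTMSTEGAKLVDRINELAGQFVDKSTRPELAMTMSTEGAKLV
DRINELAGQFVDKSTRPELAMTMSTEGAKLVDRINELAGQPQSTGAPQSTGAPQSTGAPQ
HHHHHHSTGAPQSTGAPQSTPQPQPQPQPGPQPQPQPQPSPQPQPQPQPAPQPQPQPQPT
STGAPQSTGAPQSTGAPQSTGAPQSTGAPHSTGAPQSTGAPQSTGAPQSTGAPQSTGAPH
STGAPQSTGAPQSTGAPQSTGAPQSTGAPHSTGAPQSTGAPQSTGAPQSTGAPQSTGAPH
STGAPQSTGAPQSTGAPQSTGAPQSTGAPHSTGAPQSTGAPQSTGAPQSTGAPQSTGAPH
STGAPQSTGAPQSTGAPQSTGAPQSTGAPQSTGAPQSTGAHPQPQHPQPQPQHPQPQPQP
QHPQPQPQPQHPQPQPQPQHPQPQPGSAHTGSATGSAHTGSATGSAHTGSATGSATGSAT
STGAPQSTGAPQSTGAPQSHGAPQSTGAPQSTGAPQSTGAPQSTHAPQSTGAPQSTGAPQ
STGAPQSTGHPQSTGAPQSTGAPQSTGAPQSTGAHQSTGAPQSTGAPQSTGAPQSTGAPH
STGAPQSTGAPQSTGAPQSTGAPQHTGAPQSTGAPQSTGAPQSTGAPQSHGAPQSTGAPQ
STGAPQSTGAPQSTHAPQSTGAPQSTGAPQSTGAPQSTGHPQSTGAPQSTGAPQSTGAPQ
STGAHQSTGAPQSTGAPQSTGAPQSTGAPHSTGAPQSTGAPQSTGAPQSTGAPQHTGAPQ
STGAPQSTGAPQSTGAPQST
>SYNP0001 synthetic his_cluster_in_PQ protein
HANTKQSTDVDHAVHMSVKYSWCLKGYPNQIGDLNLEYRGPLMPCFTMRGGPILQTSAKT
MQKNEANDELSEVEDLGKLRSGTIKELLATLEHHQGKQRTEEGHCQQKLRNQVKKLGRNG
PRRDPHCEDYRHHHHHHPQPQPQPQPGPQPQPQPQPGPQPQPQPQPGPQPQPQPQPGIQH
FAAQQHISAEISSLLKSQQFKNPSPMVEAKTGLPNRGKYVSKCANAELEGSALWILFKPL
KLEKVSSV
>SYNP0002 synthetic his_cluster_ordered protein
EAKLISKRRDSACVSFEHFSIVSFGAPVGVLEMGSVLGLFQAGGLQRSLVPLGFHPSAAS
MVLEHATYWPPSAKHGNDQHLSPTVKAIAPLIGLLCGIYPRLSQVDCVVKTAMTRRHGAL
AQSDMESLNRVGARNLCSLFHHHHHHYKLLKTPFSMALGSREDSSAIPLSVMIKLVGDKK
KPLHLPELVTHGFAVSITLPPDTPAATYNPLNLSTA
>SYNP0003 synthetic isolated_his protein
NGLFCVVRFSQEKNSFPFELLMVNPVSQASLSSVISFKSFESQEAVGSAGKIYISTTLYV
ANEQTPLLKVEDCVSKQTEGAFETSSLYAFQQELLAGDEVQREWLERLLRKEYTTEVMWP
DHIPWIVKGLPVAQAVVQSPVVVTGIYSEVAVREDSDAPDVGEEEKDSVNDASKIVTVGC
YECNDVVELVAQFGIEQKPIAVQLGLSEAAGVFQCAISSDKRSNNLDKCFPQVEDQDEAA
KFFGDIDGALTERSGAIGPPRPCMYLVGTRNCKKCFPLQYGE
>SYNP0004 synthetic no_his protein
SSEKSCCWDSLTTYPPKPLGEDLYFQCRTGLTSARGLNGTLRAGSISFFEKVSVEAVSYV
RDRYLLKETGLLCELELEPLGRRATYLQILKKSAGISVQAPTLKYPYMTAEANLSVGINL
IPTSVYKFQRQYSELIIAPRGGYGLDTLLGLKCGEKSGACFQQWKESQMMSRNSGSPVCF
YQLLGEQVVLGQGLDKLGPADGRRITTPTLILFLEQEPPRKLSAGDSPLPQ
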
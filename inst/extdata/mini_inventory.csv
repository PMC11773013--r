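cluster,plot,subplot,habitat,protected_area,species,dbh_cm,stem_form
c01,p1,A,humid,1,Brachystegia spiciformis,7.2,
c01,p1,,humid,1,Brachystegia spiciformis,23.5,SF1
c01,p2,,humid,0,Brachystegia spiciformis,41.0,SF1
c01,p2,,humid,0,Julbernardia globiflora,15.4,SF2
c01,p3,,humid,0,Diplorhynchus condylocarpon,11.1,SF1
c02,p1,,humid,0,Brachystegia boehmii,33.0,SF3
c02,p1,A,humid,0,Julbernardia globiflora,6.0,
c02,p2,,humid,0,Pseudolachnostylis maprouneifolia,18.9,SF1
c02,p4,,humid,0,Brachystegia spiciformis,44.7,SF2
c03,p1,,semi-arid,0,Julbernardia globiflora,12.3,SF1
c03,p2,,semi-arid,1,Combretum imberbe,27.8,SF3
c03,p3,,semi-arid,0,Julbernardia globiflora,10.0,SF1
c04,p1,,rainy,1,Uapaca kirkiana,13.6,SF1
c04,p2,,rainy,0,Brachystegia spiciformis,52.1,SF1
c04,p2,,rainy,0,Uapaca kirkiana,9.9,
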
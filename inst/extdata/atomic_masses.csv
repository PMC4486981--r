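# version: AME2020 masses / IUPAC-2021 abundances / CODATA-2018 electron
element,isotope,mass_da,abundance
e,e-,0.000548579909065,1
H,1H,1.00782503224,0.999885
H,2H,2.01410177811,0.000115
C,12C,12.0,0.9893
C,13C,13.00335483521,0.0107
N,14N,14.00307400446,0.99636
N,15N,15.00010889894,0.00364
O,16O,15.99491461960,0.99757
O,17O,16.99913175664,0.00038
O,18O,17.99915961287,0.00205
S,32S,31.97207117443,0.9499
S,33S,32.97145890985,0.0075
S,34S,33.96786701111,0.0425
S,36S,35.96708070,0.0001
Br,79Br,78.91833762,0.5069
Br,81Br,80.91628970,0.4931
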
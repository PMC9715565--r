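# ferrodom monoisotopic element masses, v1 (CODATA/AME2020, most abundant isotope)
element,isotope,mass_da
C,12C,12.000000000
H,1H,1.007825032
N,14N,14.003074004
O,16O,15.994914620
S,32S,31.972071174
P,31P,30.973761998
Cl,35Cl,34.968852682
Fe,56Fe,55.934936330
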
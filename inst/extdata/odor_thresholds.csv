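compound,threshold,unit,source
Ethyl 3-methyl butyrate,3,ug/L,a
Ethyl hexanoate,1,ug/L,b
Ethyl isobutyrate,0.1,ug/L,a
Ethyl 2-methyl butyrate,1,ug/L,c
Ethyl caprylate,2,ug/L,a
Ethyl caprate,200,ug/L,d
Ethyl heptanoate,2.2,ug/L,b
Butyric acid ethyl ester,1,ug/L,b
Ethyl valerate,5,ug/L,b
Methyl isobutyrate,7,ug/L,b
Ethyl acetate,5,ug/L,b
Isobutyl acetate,66,ug/L,b
Ethyl acrylate,67,ug/L,b
1-pentanol,150.2,ug/kg,e
2-methyl-1-butanol,250,ug/kg,f
Phenylethyl alcohol,4,ug/kg,g
2-ethyl-1-hexanol,270000,ug/kg,b
Hexyl alcohol,500,ug/kg,f
Phenylacetaldehyde,800,ug/kg,e
Nonanal,1,ug/kg,e
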
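compound,formula,class,odor,blank,wild,mutagenic
Ethyl 3-methyl butyrate,,ester,Fruity,-,20.77,23.52
Ethyl hexanoate,,ester,Fruity,-,15.44,11.86
Ethyl isobutyrate,,ester,Fruity,-,8.03,8.48
Ethyl 2-methyl butyrate,,ester,Fruity,-,7.33,7.48
Methyl 3-methyl-2-butenoate,C6H10O2,ester,,-,5.82,6.12
Ethyl 3-methyl-2-butenoate,C7H12O2,ester,,-,5.20,4.43
Ethyl caprylate,,ester,Waxy,-,4.58,5.30
Ethyl caprate,,ester,Waxy,-,3.15,3.32
Butyl 3-methyl-2-butenoate,C9H16O2,ester,,-,2.99,-
Butyl 3-methyl acetate,C7H14O2,ester,,-,2.27,2.44
Ethyl heptanoate,,ester,Fruity,-,2.11,1.66
Isobutyl isovalerate,C9H18O2,ester,"Fruity, green",-,2.10,-
Butyric acid ethyl ester,,ester,Fruity,-,1.88,2.00
Methyl isovalerate,,ester,Fruity,-,1.69,1.87
Methyl 2-methylbutyrate,,ester,Fruity,-,1.24,1.44
Ethyl valerate,,ester,Fruity,-,1.07,0.81
Isobutyl isobutyrate,,ester,Fruity,-,1.05,0.59
"Butanoic acid, 2-methyl-, 2-methyl propyl ester",,ester,,-,0.88,-
Methyl isobutyrate,,ester,,-,0.80,-
"2-hexenoic acid, ethylester",,ester,Fruity,-,0.76,0.66
Ethyl acetate,,ester,Ethereal,8.07,0.71,0.97
Ethyl trans-4-decenoate,,ester,"Green, fatty",-,0.59,0.64
Isobutyl acetate,,ester,Fruity,-,0.34,0.35
Butyl 2-methyl acetate,,ester,,-,0.31,0.36
Ethyl acrylate,,ester,Plastic,-,0.30,-
Ethyl nonanoate,,ester,Waxy,-,0.28,0.31
Ethyl (E)-2-octenoate,,ester,Fruity,-,0.27,0.31
Ethyl propionate,,ester,Fruity,-,-,0.81
"Propanoic acid, 2-methyl-, 3-methylbutyl ester",,ester,Fruity,-,-,0.56
Phenethyl butyrate,,ester,"Floral, fruity",-,-,0.30
1-pentanol,,alcohol,"Fusel, fermented",17.86,1.29,1.51
2-methyl-1-butanol,,alcohol,Ethereal,6.68,0.92,1.06
Phenylethyl alcohol,,alcohol,Floral,-,-,7.63
2-ethyl-1-hexanol,,alcohol,"Citrus, fatty",12.11,-,0.33
Hexyl alcohol,,alcohol,"Herbal, green",8.23,-,-
Phenylacetaldehyde,,aldehyde,"Green, honey",3.92,8.98,0.46
Nonanal,,aldehyde,"Grassy, almond",37.60,-,-
Benzene,,other,"Fragrance, sweet",7.36,-,0.29
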
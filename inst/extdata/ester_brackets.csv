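formula,ref_low,ref_high
C6H10O2,Ethyl 3-methyl butyrate,Ethyl acetate
C7H12O2,Ethyl 3-methyl butyrate,Ethyl hexanoate
C9H16O2,Ethyl caprylate,Ethyl heptanoate
C7H14O2,Ethyl 3-methyl butyrate,
C9H18O2,Ethyl heptanoate,
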
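srna,rank,mrna,category,binding
SroE,3,yieH,top_ranked,no
SroE,5,yeaG,top_ranked,no
SroE,9,yahN,top_ranked,no
SroE,10,mdtA,top_ranked,no
SroE,12,creA,top_ranked,no
SroE,18,arcC,informed,no
SroE,32,pdxY,informed,no
SroE,38,marC,informed,no
SroE,46,ligB,informed,weak
SroE,61,fadH,informed,no
SroG,4,cdsA,both,yes
SroG,5,cysJ,both,yes
SroG,7,yfbR,both,yes
SroG,10,yncD,both,yes
SroG,12,mepM,both,yes
SroG,64,potA,informed,yes
SroG,65,dosP,informed,no
SroG,75,pgl,informed,yes
SroG,76,fecE,informed,weak
Tpke70,3,agaS,top_ranked,weak
Tpke70,6,dkgB,both,no
Tpke70,7,mcrA,both,yes
Tpke70,12,mdoB,both,no
Tpke70,13,dbpA,both,no
Tpke70,14,degS,both,no
Tpke70,19,torT,informed,yes
Tpke70,29,glnK,informed,yes
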
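(Phacochoerus_africanus:11,((Sus_barbatus:3.0,(Sus_verrucosus:2.5,(Sus_cebifrons:2.2,Sus_celebensis:2.2)2.2:0.3)2.5:0.5)3.0:0.5,(Sumatra:2.0,((Europe_domestic:0.01,Europe_wild:0.01)0.01:0.99,((SouthChina_wild:0.01,SouthChina_domestic:0.01)0.01:0.59,(Tibetan_wild:0.2,(NorthChina_wild:0.01,NorthChina_domestic:0.01)0.01:0.19)0.2:0.4)0.6:0.4)1.0:1.0)2.0:1.5)3.5:7.5)11;
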
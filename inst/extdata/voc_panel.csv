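voc,class,indoor_median,indoor_gsd,outdoor_median,outdoor_gsd
ethanol,oxygenate,320,3.0,5,1.8
methanol,oxygenate,80,2.5,5,1.8
isopropanol,oxygenate,40,3.0,1,1.8
propane,alkane,90,2.5,2,1.8
n-butane,alkane,120,2.5,3,1.8
acetaldehyde,carbonyl,15,2.0,1.5,1.8
propanal,carbonyl,2,2.0,0.3,1.8
"1,3-butadiene",alkene,2,2.5,0.3,1.8
benzene,btex,0.5,1.8,0.18,1.8
toluene,btex,1.5,2.2,0.30,1.8
ethylbenzene,btex,0.4,2.2,0.10,1.8
xylene,btex,1.2,2.2,0.20,1.8
"1,2,4-trimethylbenzene",tmb,0.4,2.2,0.05,1.8
"1,3,5-trimethylbenzene",tmb,0.15,2.2,0.02,1.8
alpha-pinene,monoterpene,4,2.5,0.2,1.8
limonene,monoterpene,15,2.8,0.3,1.8
carbon tetrachloride,halocarbon,15,1.5,0.6,1.2
chloroform,halocarbon,2,2.0,0.1,1.5
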
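voc,iur,rfc,provenance
acetaldehyde,2.2e-06,9,IRIS
benzene,7.8e-06,30,IRIS
"1,3-butadiene",3.0e-05,2,IRIS
carbon tetrachloride,6.0e-06,100,IRIS
chloroform,2.3e-05,,IRIS
ethylbenzene,,1000,IRIS
toluene,,5000,IRIS
xylene,,100,IRIS
"1,2,4-trimethylbenzene",,60,IRIS
methanol,,20000,IRIS
propanal,,8,IRIS
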
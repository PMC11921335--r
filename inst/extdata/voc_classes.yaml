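# VOC class membership used for class totals, the outlier-treatment scope
# and the urban outdoor aromatic shift. Edit or pass a copy to
# voc_classes(path = ...). "aromatics" (btex + tmb) is derived if absent.
btex:
  - benzene
  - toluene
  - ethylbenzene
  - xylene
tmb:
  - "1,2,4-trimethylbenzene"
  - "1,3,5-trimethylbenzene"
monoterpenes:
  - alpha-pinene
  - limonene
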
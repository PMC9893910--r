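scenario,endpoint_group,value
base,ecosystem,1.41e-06
BMP1,ecosystem,1.34e-06
BMP2,ecosystem,1.28e-06
base,human_health,2.58e-07
BMP1,human_health,2.40e-07
BMP2,human_health,2.22e-07
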
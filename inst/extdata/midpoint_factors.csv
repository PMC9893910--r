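pollutant,emission_compartment,category,factor,unit
NO3,freshwater,marine_eutrophication,0.07,kg N-eq/kg
NO2,freshwater,marine_eutrophication,0.09,kg N-eq/kg
P,freshwater,freshwater_eutrophication,1,kg P-eq/kg
PO4,freshwater,freshwater_eutrophication,33,kg P-eq/kg
NO3,marine,marine_eutrophication,0.23,kg N-eq/kg
NO2,marine,marine_eutrophication,0.3,kg N-eq/kg
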
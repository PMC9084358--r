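sector,category
coal,IFF
oil,IFF
gas,IFF
oil_gas,IFF
enteric,AGW
manure,AGW
livestock,AGW
rice,AGW
landfill,AGW
waste,AGW
wetland,WET
wetland_tropical,WET
wetland_boreal,WET
biomass_burning,BB
geological,GEO
termites,OTH
freshwater,OTH
wild_animals,OTH
soil_uptake,SOIL
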
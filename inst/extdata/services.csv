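"service","OPEN_WATER","LOW_TIDAL","SALTMARSH","TRANSITIONAL","DRY_UNDEVELOPED","DRY_DEVELOPED","edge","width"
"carbon_sequestration",0,0,2,1.5,0,0,0,0
"nitrogen_sequestration",0,0,2.5,1.8,0,0,0,0
"phosphorus_sequestration",0,0,1.2,0.9,0,0,0,0
"dry_land_recreation",0,0,0,0,1,0,0,0
"marsh_recreation",0,0,0.5,1,0,0,0,0
"underserved_natural_areas",0,0,1,1,1,0,0,0
"nekton_habitat",0,0.5,1,0,0,0,0.02,0
"habitat_connectivity",0,0,1,1,0,0,0.01,0
"flood_protection",0,0,0.5,0.5,0,0,0,0.05
"cultural_historic",0,0,0.8,0.8,0.4,0,0,0
"natural_area_preservation",0,0.5,1,1,0.5,0,0,0
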
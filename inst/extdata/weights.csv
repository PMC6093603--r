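"service","weight_pct"
"carbon_sequestration",7.6
"nitrogen_sequestration",8.2
"phosphorus_sequestration",7.5
"dry_land_recreation",4.5
"marsh_recreation",4.5
"underserved_natural_areas",8.1
"nekton_habitat",13.6
"habitat_connectivity",17.7
"flood_protection",14
"cultural_historic",5.5
"natural_area_preservation",8.7
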
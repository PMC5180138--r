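item,habitat,cost_eur_ha_yr_low,cost_eur_ha_yr_high,note
transmission_corridor_maintenance,transmission_corridor,60,60,current mechanical maintenance on the eight-year cycle
roadside_mowing,maintained_roadside,500,1000,annual mowing of quiet tertiary/quaternary roadsides
agri_environment_scheme,seminatural_grassland,121,506,EU AES funding for grassland maintenance and enhancement
nectar_flower_sowing,any,42,42,sowing of nectar-rich flower seed
shrub_removal,transmission_corridor,14,14,removal of existing shrubs
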
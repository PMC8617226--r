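indicator_id,factor_id,factor_name,dimension,direction,entity_level
area_2006,E1,area,ecological,+,stock
area_2100,E1,area,ecological,+,stock
ssb_trend_historic,E2,abundance,ecological,+,stock
ssb_trend_recent,E2,abundance,ecological,+,stock
f_trend,E2,abundance,ecological,-,stock
r_trend,E2,abundance,ecological,+,stock
t50,E3,temperature,ecological,+,stock
t_range,E3,temperature,ecological,+,stock
overmsy,E4,overexploitation,ecological,-,stock
kobe_status,E4,overexploitation,ecological,+,stock
recovery_time,E5,recovery,ecological,-,stock
gear_count,S1,gear_diversity,socioeconomic,+,country
ices_areas_recent,S2,fleet_mobility,socioeconomic,+,country
ices_areas_delta,S2,fleet_mobility,socioeconomic,+,country
stockdep_species,S3,catch_dependency,socioeconomic,-,country
stockdep_total,S3,catch_dependency,socioeconomic,-,country
research_investment,S4,adaptive_management,socioeconomic,+,country
management_investment,S4,adaptive_management,socioeconomic,+,country
n_organizations,I1,co_management,institutional,+,country
swap_earnings,I2,property_rights,institutional,+,country
above_tac,I3,quotas,institutional,-,country
compliance,I4,strength,institutional,+,country
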
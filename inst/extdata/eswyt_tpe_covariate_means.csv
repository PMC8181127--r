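type,variable,units,tpe1,tpe2,tpe3
MV,avg_temp,degC,15.82,18.7,21.43
MV,max_temp,degC,24.26,27.27,30.69
MV,min_temp,degC,9.5,11.69,13.72
MV,cooling_degree_days,degC_d,16.88,19.48,22.2
MV,dew_point,degC,0.65,6.18,4.24
MV,precipitation,mm,12.76,7.83,4.37
MV,rel_humidity,pct,38.29,46.87,35.77
MV,clear_sky_insolation,kWh_m2_day,-18.47,-13.12,7.68
MV,wind_speed,m_s,1.59,1.68,1.86
SV,soil_water_capacity,pct_vol,15.2,13.12,8.72
SV,soil_water_wilting,pct_vol,20.4,22.87,27.5
SV,cation_exchange,cmolc_kg,14.47,18.75,35.5
SV,coarse_fragments,pct_vol,5.467,7.75,15.4
SV,soil_organic_carbon,kg_m3,94.27,118.37,124
SV,soil_ph,pH,7.53,6.91,7.43
SV,clay_content,pct_mass,25.2,30,40.4
SV,sand_content,pct_mass,37.4,32.2,32.3
SV,silt_content,pct_mass,37.4,38,27.5
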
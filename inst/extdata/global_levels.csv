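indicator_id,period,value
undernourishment,start,13
undernourishment,end,10
food_insecurity,start,23
food_insecurity,end,29
child_mortality,start,75
child_mortality,end,42
health_coverage,start,79
health_coverage,end,28
illiteracy,start,23
illiteracy,end,16
secondary_education,start,61
secondary_education,end,37
poverty,start,85
poverty,end,73
youth_neet,start,25
youth_neet,end,21
drinking_water,start,39
drinking_water,end,37
sanitation,start,66
sanitation,end,42
electricity,start,21
electricity,end,8
clean_fuels,start,50
clean_fuels,end,27
public_transport,end,53
internet,start,93
internet,end,37
housing,start,40
housing,end,32
gender_inequality,start,46
gender_inequality,end,35
social_support,start,21
social_support,end,24
income_inequality,start,72
income_inequality,end,65
political_voice,start,46
political_voice,end,71
corruption,start,80
corruption,end,75
homicide,start,29
homicide,end,20
co2,start,370
co2,end,416
radiative_forcing,start,1.8
radiative_forcing,end,2.8
ocean_acidification,start,2.99
ocean_acidification,end,2.80
chemical_pollution,start,933
chemical_pollution,end,1964
phosphorus,start,14
phosphorus,end,23
nitrogen,start,134
nitrogen,end,193
aerosols,start,0.08
aerosols,end,0.08
blue_water,start,18.2
blue_water,end,18.2
green_water,start,15.9
green_water,end,19.3
forest,start,39
forest,end,38
extinctions,start,100
extinctions,end,100
hanpp,start,15
hanpp,end,17
ozone,start,283.0
ozone,end,283.4
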
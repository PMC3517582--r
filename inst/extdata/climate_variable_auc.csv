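index,variable,mean_auc,selected
1,Mean_temperature,0.96,0
2,Mean_temperature_in_warmest_month,0.9,0
3,Mean_temperature_in_coolest_month,0.97,1
4,Standard_deviation_of_mean_temperature,0.88,1
5,Mean_daily_precipitation,0.8,0
6,Mean_daily_precipitation_in_wettest_month,0.8,0
7,Mean_daily_precipitation_in_warmest_month,0.87,1
8,Mean_daily_precipitation_in_driest_month,0.81,0
9,Mean_daily_precipitation_in_coolest_month,0.9,1
10,Standard_deviation_of_mean_precipitation,0.83,0
11,Mean_daily_precipitation_in_coolest_quarter,0.87,0
12,Mean_daily_precipitation_in_driest_quarter,0.8,0
13,Mean_daily_precipitation_in_warmest_quarter,0.86,0
14,Mean_daily_precipitation_in_wettest_quarter,0.8,0
15,Mean_temperature_in_coolest_quarter,0.97,0
16,Mean_temperature_in_warmest_quarter,0.91,0
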
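variable,Mean_temperature,Mean_temperature_in_warmest_month,Mean_temperature_in_coolest_month,Standard_deviation_of_mean_temperature,Mean_daily_precipitation,Mean_daily_precipitation_in_wettest_month,Mean_daily_precipitation_in_warmest_month,Mean_daily_precipitation_in_driest_month,Mean_daily_precipitation_in_coolest_month,Standard_deviation_of_mean_precipitation,Mean_daily_precipitation_in_coolest_quarter,Mean_daily_precipitation_in_driest_quarter,Mean_daily_precipitation_in_warmest_quarter,Mean_daily_precipitation_in_wettest_quarter,Mean_temperature_in_coolest_quarter,Mean_temperature_in_warmest_quarter
Mean_temperature,1.0,0.61,0.87,-0.05,-0.34,-0.22,-0.21,-0.32,-0.15,-0.19,-0.2,-0.34,-0.34,-0.25,0.91,0.71
Mean_temperature_in_warmest_month,0.61,1.0,0.2,0.73,-0.27,-0.24,0.21,0.12,-0.21,-0.19,-0.22,-0.03,-0.06,-0.25,0.26,0.99
Mean_temperature_in_coolest_month,0.87,0.2,1.0,-0.46,-0.14,-0.01,-0.44,-0.51,0.07,0.0,0.01,-0.43,-0.43,-0.05,0.99,0.32
Standard_deviation_of_mean_temperature,-0.05,0.73,-0.46,1.0,-0.07,-0.12,0.55,0.53,-0.15,-0.08,-0.12,0.33,0.3,-0.11,-0.4,0.64
Mean_daily_precipitation,-0.34,-0.27,-0.14,-0.07,1.0,0.97,0.1,0.19,0.95,0.94,0.97,0.34,0.29,0.98,-0.21,-0.31
Mean_daily_precipitation_in_wettest_month,-0.22,-0.24,-0.01,-0.12,0.97,1.0,-0.05,0.01,0.99,0.99,0.99,0.15,0.09,1.0,-0.09,-0.26
Mean_daily_precipitation_in_warmest_month,-0.21,0.21,-0.44,0.55,0.1,-0.05,1.0,0.97,-0.1,-0.09,-0.06,0.88,0.87,-0.02,-0.39,0.18
Mean_daily_precipitation_in_driest_month,-0.32,0.12,-0.51,0.53,0.19,0.01,0.97,1.0,-0.04,-0.03,0.01,0.94,0.93,0.06,-0.47,0.08
Mean_daily_precipitation_in_coolest_month,-0.15,-0.21,0.07,-0.15,0.95,0.99,-0.1,-0.04,1.0,0.99,1.0,0.11,0.06,0.98,-0.01,-0.22
Standard_deviation_of_mean_precipitation,-0.19,-0.19,0.0,-0.08,0.94,0.99,-0.09,-0.03,0.99,1.0,0.99,0.1,0.04,0.99,-0.08,-0.21
Mean_daily_precipitation_in_coolest_quarter,-0.2,-0.22,0.01,-0.12,0.97,0.99,-0.06,0.01,1.0,0.99,1.0,0.16,0.1,0.99,-0.06,-0.24
Mean_daily_precipitation_in_driest_quarter,-0.34,-0.03,-0.43,0.33,0.34,0.15,0.88,0.94,0.11,0.1,0.16,1.0,0.99,0.2,-0.41,-0.05
Mean_daily_precipitation_in_warmest_quarter,-0.34,-0.06,-0.43,0.3,0.29,0.09,0.87,0.93,0.06,0.04,0.1,0.99,1.0,0.14,-0.4,-0.08
Mean_daily_precipitation_in_wettest_quarter,-0.25,-0.25,-0.05,-0.11,0.98,1.0,-0.02,0.06,0.98,0.99,0.99,0.2,0.14,1.0,-0.12,-0.27
Mean_temperature_in_coolest_quarter,0.91,0.26,0.99,-0.4,-0.21,-0.09,-0.39,-0.47,-0.01,-0.08,-0.06,-0.41,-0.4,-0.12,1.0,0.38
Mean_temperature_in_warmest_quarter,0.71,0.99,0.32,0.64,-0.31,-0.26,0.18,0.08,-0.22,-0.21,-0.24,-0.05,-0.08,-0.27,0.38,1.0
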
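node,Standard_deviation_of_mean_temperature_max,Standard_deviation_of_mean_temperature_min,Mean_daily_precipitation_in_warmest_month_max,Mean_daily_precipitation_in_warmest_month_min,Mean_daily_precipitation_in_coolest_month_max,Mean_daily_precipitation_in_coolest_month_min,Mean_temperature_in_coolest_month_max,Mean_temperature_in_coolest_month_min
40,10.3,7.1,1.3,0.1,5.5,0.1,3.6,-5.0
41,9.8,7.4,0.6,0.1,4.8,0.1,2.8,-3.3
42,9.7,7.2,0.5,0.1,4.8,0.1,2.5,-2.9
43,9.4,6.9,0.4,0.1,4.7,0.1,3.0,-1.7
44,9.3,6.6,0.4,0.1,5.0,0.1,3.2,-1.5
45,9.2,6.4,0.4,0.1,5.1,0.1,3.4,-1.3
46,9.1,6.3,0.4,0.1,5.2,0.1,3.4,-1.3
47,8.9,6.3,0.3,0.1,5.2,0.1,3.1,-1.2
48,8.5,6.9,0.2,0.1,4.7,0.1,2.0,-1.1
49,8.9,7.1,0.1,0.1,4.6,0.1,1.4,-1.7
50,8.9,5.8,0.3,0.1,5.9,0.1,3.5,-0.9
51,9.6,7.6,0.3,0.1,5.3,0.1,0.0,-4.1
52,9.1,6.2,0.4,0.1,5.3,0.1,3.6,-1.4
53,9.0,5.5,0.5,0.1,5.4,0.1,4.6,-1.7
54,9.1,4.3,0.4,0.1,5.2,0.1,7.5,0.4
55,9.0,4.6,0.4,0.0,3.6,0.0,8.5,2.3
56,8.7,5.9,0.2,0.0,2.7,0.0,7.2,2.4
57,9.0,6.3,0.4,0.1,5.8,0.1,3.5,-1.4
58,8.8,5.7,0.3,0.0,4.6,0.0,6.6,2.7
59,8.9,6.4,0.4,0.1,6.3,0.1,2.8,-2.2
60,8.5,6.0,0.3,0.1,7.8,0.1,2.8,-2.3
61,9.1,6.8,0.3,0.1,6.3,0.1,1.9,-3.2
62,9.0,6.8,0.3,0.1,6.5,0.1,2.0,-3.0
63,9.3,7.5,0.4,0.1,6.0,0.1,0.5,-4.9
64,9.5,7.4,0.5,0.1,6.5,0.1,0.8,-5.5
65,9.4,8.1,0.4,0.2,5.3,0.2,-1.1,-5.8
66,8.7,5.0,0.4,0.1,4.7,0.1,6.8,2.5
67,9.2,6.1,0.3,0.1,2.7,0.1,6.7,3.3
68,9.7,7.7,0.5,0.1,4.4,0.1,2.7,-2.9
69,9.4,7.7,0.3,0.1,4.6,0.1,3.3,-2.1
70,9.2,7.8,0.3,0.1,4.7,0.1,3.3,-1.4
71,10.0,8.1,0.4,0.1,3.7,0.1,2.2,-3.1
72,9.8,7.5,0.2,0.1,4.2,0.1,3.8,-1.9
73,9.5,7.2,0.1,0.1,4.6,0.1,3.3,-1.5
74,10.2,8.7,0.4,0.1,3.0,0.1,0.8,-3.9
75,10.2,8.9,0.4,0.2,2.8,0.2,0.5,-3.8
76,10.3,8.8,0.4,0.2,2.8,0.2,0.3,-4.1
77,10.2,8.6,0.3,0.1,3.0,0.1,-0.3,-4.5
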
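species,n_locations,Standard_deviation_of_mean_temperature_max,Standard_deviation_of_mean_temperature_min,Mean_daily_precipitation_in_warmest_month_max,Mean_daily_precipitation_in_warmest_month_min,Mean_daily_precipitation_in_coolest_month_max,Mean_daily_precipitation_in_coolest_month_min,Mean_temperature_in_coolest_month_max,Mean_temperature_in_coolest_month_min
Horkelia bolanderi,14,8.0,2.5,0.4,0.0,7.3,0.5,9.4,4.2
Horkelia californica,123,9.4,2.5,0.5,0.0,7.3,1.3,9.4,-0.1
Horkelia cuneata,42,9.4,2.8,0.5,0.0,4.1,0.7,11.0,3.2
Horkelia daucifolia,35,8.2,5.8,0.3,0.0,8.4,5.3,4.2,-4.0
Horkelia fusca,256,10.0,5.8,1.0,0.0,8.4,1.5,4.6,-8.5
Horkelia hendersonii,11,7.2,5.8,0.3,0.1,8.4,4.2,2.9,0.8
Horkelia hispidula,11,8.9,7.2,0.1,0.1,4.2,2.2,0.8,-0.8
Horkelia marinensis,16,7.8,2.5,0.4,0.0,7.3,4.8,9.4,4.2
Horkeliella congdonis,15,7.6,7.2,0.1,0.1,4.4,3.5,1.8,-0.1
Horkeliella purpurascens,20,8.9,7.2,0.1,0.0,4.2,1.5,4.6,-0.8
Horkelia rydbergii,39,9.9,8.7,0.1,0.0,1.5,1.2,4.6,2.4
Horkelia tenuiloba,18,7.8,2.5,0.4,0.0,7.3,4.8,9.4,4.2
Horkelia tridentata,116,9.0,5.8,0.3,0.0,8.4,3.5,4.2,-2.8
Horkelia truncata,24,8.4,5.3,0.3,0.0,0.7,0.5,9.2,5.7
Horkelia wilderae,10,9.9,9.9,0.1,0.1,1.2,1.2,2.4,2.4
Horkelia yadonii,10,8.7,2.8,0.5,0.0,3.4,0.8,11.0,4.6
Ivesia aperta,26,9.0,9.0,0.1,0.1,4.9,4.9,-2.8,-2.8
Ivesia argyrocoma,25,9.9,9.4,0.1,0.1,1.3,1.2,3.2,2.4
Ivesia arizonica,11,10.5,8.7,0.5,0.1,2.5,1.0,0.1,-5.7
Ivesia baileyi,51,10.5,7.8,0.4,0.1,5.3,1.2,-2.1,-7.1
Ivesia cryptocaulis,2,9.8,9.8,0.2,0.2,1.4,1.4,-2.3,-2.3
Ivesia jaegeri,13,9.9,9.8,0.2,0.1,1.4,1.2,2.4,-2.3
Ivesia kingii,24,10.6,7.2,0.5,0.1,4.9,1.0,0.8,-7.1
Ivesia longibracteata,5,8.2,6.3,0.2,0.0,8.1,6.4,4.2,1.6
Ivesia lycopodioides,83,9.0,7.2,0.1,0.0,4.9,1.5,4.6,-2.8
Ivesia multifoliolata,12,10.3,10.3,0.3,0.3,1.0,1.0,-0.3,-0.3
Ivesia pygmaea,32,9.0,7.2,0.1,0.1,4.9,3.5,1.8,-2.8
Ivesia rhypara,29,9.4,5.8,0.4,0.1,8.4,1.8,2.7,-5.5
Ivesia sabulosa,19,10.6,9.7,0.5,0.2,2.4,1.0,-0.3,-7.1
Ivesia santolinoides,57,9.9,7.2,0.1,0.0,4.4,1.2,4.6,-0.1
Ivesia saxosa,20,9.9,7.2,0.1,0.0,4.2,0.5,6.8,-0.8
Ivesia sericoleuca,23,9.0,9.0,0.1,0.1,4.9,4.9,-2.8,-2.8
Ivesia setosa,41,10.5,7.8,0.4,0.1,5.3,1.2,-2.1,-7.1
Ivesia shockleyi,27,10.5,7.2,0.4,0.1,5.3,1.3,0.8,-7.1
Ivesia tweedyi,36,8.4,6.2,1.0,0.3,6.2,3.2,0.4,-6.9
Ivesia unguiculata,15,9.0,7.2,0.1,0.1,4.9,3.5,1.8,-2.8
Ivesia utahensis,10,10.6,10.6,0.5,0.4,1.8,1.0,-7.1,-8.2
Ivesia webberi,10,9.0,7.6,0.1,0.1,4.9,4.4,-0.1,-2.8
Potentilla biennis,333,12.1,5.8,3.8,0.0,8.4,0.5,6.8,-12.1
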
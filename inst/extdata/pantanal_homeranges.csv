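species,animal_id,sex,locations,ud_km2,pct_day,pct_night,days_monitored
ocelot,LP1,Female,77,7.0,53.2,46.8,618
ocelot,LP2,Female,52,4.5,50.0,50.0,613
ocelot,LP3,Female,42,8.0,73.8,26.2,348
ocelot,LP4,Female,21,8.8,52.4,47.6,85
ocelot,LP5,Male,59,16.1,50.8,49.2,502
ocelot,LP6,Male,34,3.8,61.8,38.2,169
crab-eating fox,CT1,Female,53,2.3,37.7,62.3,350
crab-eating fox,CT2,Male,86,1.2,62.1,37.9,472
crab-eating fox,CT3,Male,83,1.4,48.6,51.4,774
crab-eating fox,CT4,Female,93,2.2,50.4,49.6,427
crab-eating fox,CT5,Female,79,1.7,62.7,37.3,473
crab-eating fox,CT6,Female,65,1.0,58.1,41.9,471
crab-eating fox,CT7,Male,45,0.9,56.8,43.2,298
brown-nosed coati,NN1,Female,66,3.4,59.1,40.9,823
brown-nosed coati,NN2,Female,57,3.6,66.7,33.3,287
brown-nosed coati,NN3,Female,51,1.5,82.4,17.6,486
brown-nosed coati,NN4,Female,39,1.5,61.5,38.5,171
brown-nosed coati,NN5,Male,33,1.2,51.5,48.5,354
brown-nosed coati,NN6,Male,55,0.6,76.4,23.6,472
brown-nosed coati,NN7,Male,19,1.4,47.4,52.6,155
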
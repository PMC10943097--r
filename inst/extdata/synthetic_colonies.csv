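"site","shelf","year","month","transect","genus","area_cm2","bleached","partial_mortality","partially_captured"
"South","offshore",2010,10,1,"Pocillopora",38.88,1,0,0
"South","offshore",2010,10,1,"Pocillopora",16.344,0,0,1
"South","offshore",2010,10,1,"Pocillopora",5.917,1,0,0
"South","offshore",2010,10,1,"Pocillopora",6.334,1,1,0
"South","offshore",2010,10,1,"Pocillopora",1.332,0,0,0
"South","offshore",2010,10,1,"Pocillopora",15.84,0,0,1
"South","offshore",2010,10,1,"Turbinaria",10.527,0,0,0
"South","offshore",2010,10,1,"Turbinaria",538.489,0,0,0
"South","offshore",2010,10,1,"Turbinaria",73.599,1,0,0
"South","offshore",2010,10,1,"Turbinaria",36.242,0,0,0
"South","offshore",2010,10,1,"Turbinaria",391.404,1,0,0
"South","offshore",2010,10,1,"Turbinaria",1164.961,0,0,0
"South","offshore",2016,4,1,"Pocillopora",138.627,0,0,0
"South","offshore",2016,4,1,"Pocillopora",6.641,1,0,0
"South","offshore",2016,4,1,"Pocillopora",11.391,1,0,0
"South","offshore",2016,4,1,"Pocillopora",11.578,0,0,0
"South","offshore",2016,4,1,"Pocillopora",5.058,0,0,0
"South","offshore",2016,4,1,"Pocillopora",8.604,1,0,0
"South","offshore",2016,4,1,"Turbinaria",183.9,1,0,0
"South","offshore",2016,4,1,"Turbinaria",160.187,0,0,0
"South","offshore",2016,4,1,"Turbinaria",34.374,1,0,0
"South","offshore",2016,4,1,"Turbinaria",271.03,0,0,0
"South","offshore",2016,4,1,"Turbinaria",473.268,0,0,0
"South","offshore",2016,4,1,"Turbinaria",12.877,0,0,0
"South","offshore",2019,10,1,"Pocillopora",7.472,0,1,0
"South","offshore",2019,10,1,"Pocillopora",11.948,0,0,0
"South","offshore",2019,10,1,"Pocillopora",86.746,0,0,0
"South","offshore",2019,10,1,"Pocillopora",70.911,0,0,0
"South","offshore",2019,10,1,"Pocillopora",0.981,1,0,0
"South","offshore",2019,10,1,"Pocillopora",2.646,1,0,0
"South","offshore",2019,10,1,"Turbinaria",264.476,0,0,0
"South","offshore",2019,10,1,"Turbinaria",106.586,0,0,0
"South","offshore",2019,10,1,"Turbinaria",150.053,1,0,0
"South","offshore",2019,10,1,"Turbinaria",11.71,1,0,0
"South","offshore",2019,10,1,"Turbinaria",915.773,0,0,0
"South","offshore",2019,10,1,"Turbinaria",225.511,0,0,0
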
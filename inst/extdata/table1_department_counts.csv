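department_id,department_name,region,count_insurance,count_network,count_hospital,unique_observed
57,Moselle,NE,1298,1161,2507,3036
55,Meuse,NE,244,296,226,395
54,Meurthe-et-Moselle,NE,918,1425,1112,1799
88,Vosges,NE,373,580,450,731
22,Cotes-dArmor,NW,579,258,868,975
29,Finistere,NW,837,370,961,1203
35,Ille-et-Vilaine,NW,751,717,904,1275
56,Morbihan,NW,511,353,796,934
03,Allier,C,413,84,398,498
43,Haute-Loire,C,209,39,148,214
63,Puy-de-Dome,C,591,373,301,638
15,Cantal,C,152,87,118,189
69,Rhone,SE,1429,1932,1237,2336
46,Lot,SW,146,116,183,244
12,Aveyron,SW,240,141,257,347
82,Tarn-et-Garonne,SW,167,133,145,232
81,Tarn,SW,306,259,418,539
32,Gers,SW,156,125,177,247
31,Haute-Garonne,SW,940,1054,1420,1812
65,Hautes-Pyrenees,SW,152,120,21,136
09,Ariege,SW,119,120,185,233
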
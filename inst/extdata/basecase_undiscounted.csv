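label,cost,life_years,qaly
No screening,373,46.2328,35.1146
Age 35-49 every five years,755,46.2434,35.1225
Age 35-49 every four years,883,46.2487,35.1264
Age 35-49 every three years,1008,46.2528,35.1295
Age 35-49 every two years,1385,46.2642,35.1382
Age 35-49 every year,2250,46.2722,35.1445
Age >=50 every five years,1279,46.2953,35.1607
Age >=50 every four years,1495,46.3102,35.1717
Age >=50 every three years,1833,46.3304,35.1877
Age >=50 every two years,2506,46.3600,35.2104
Age >=50 every year,4468,46.3938,35.2379
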
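label,cost,life_years,qaly
No screening,195,24.2034,18.3857
Age 35-49 every five years,529,24.2091,18.3899
Age 35-49 every four years,629,24.2118,18.3919
Age 35-49 every three years,736,24.2139,18.3936
Age 35-49 every two years,1033,24.2191,18.3977
Age >=50 every five years,600,24.2217,18.3993
Age 35-49 every year,1745,24.2229,18.4008
Age >=50 every four years,692,24.2259,18.4024
Age >=50 every three years,837,24.2314,18.4069
Age >=50 every two years,1119,24.2394,18.4131
Age >=50 every year,1915,24.2483,18.4206
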
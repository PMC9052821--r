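band,f_center_hz,f_lo_hz,f_hi_hz,importance,internal_noise_db,standard_speech_db
1,150,100,200,0.0103,1.5,31.44
2,250,200,300,0.0261,-3.9,34.75
3,350,300,400,0.0419,-7.2,34.14
4,450,400,510,0.0577,-8.9,34.58
5,570,510,630,0.0577,-10.3,33.17
6,700,630,770,0.0577,-11.4,30.64
7,840,770,920,0.0577,-12.0,27.59
8,1000,920,1080,0.0577,-12.5,25.01
9,1170,1080,1270,0.0577,-13.2,23.52
10,1370,1270,1480,0.0577,-14.0,22.28
11,1600,1480,1720,0.0577,-15.4,20.15
12,1850,1720,2000,0.0577,-16.9,18.29
13,2150,2000,2320,0.0577,-18.8,16.37
14,2500,2320,2700,0.0577,-21.2,13.80
15,2900,2700,3150,0.0577,-23.2,12.21
16,3400,3150,3700,0.0577,-24.9,11.09
17,4000,3700,4400,0.0577,-25.9,9.33
18,4800,4400,5300,0.0460,-24.2,5.84
19,5800,5300,6400,0.0343,-22.6,3.47
20,7000,6400,7700,0.0226,-19.0,1.78
21,8500,7700,9500,0.0110,-15.2,-0.14
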
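freq_hz,level_db
100,54.4
125,57.7
160,56.8
200,60.2
250,60.3
315,59.0
400,62.1
500,62.1
630,60.5
800,56.8
1000,53.7
1250,53.0
1600,52.0
2000,48.7
2500,48.1
3150,46.8
4000,45.6
5000,44.5
6300,44.3
8000,43.7
10000,43.4
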
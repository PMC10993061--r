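pair,psnr_db,ssim
1,24.910412182823,0.979894805724
2,22.853856201819,0.966896295308
3,16.675961071854,0.876165184375
4,16.318089936137,0.863334761220
5,15.457536934277,0.843379495575
6,15.303587542552,0.824022973349
7,22.434842232538,0.965149347887
8,22.365485797093,0.963466369555
9,19.874296565664,0.935655945765
10,22.504681085316,0.964345993736
11,21.426735728605,0.956119850032
12,15.483486030288,0.836581499656
13,32.526099294772,0.996523433499
14,15.879721468735,0.853362470579
15,16.040389906788,0.856751116342
16,19.922047173967,0.942017875859
17,25.016917899413,0.981146916623
18,27.925630534845,0.989825406537
19,22.764774446691,0.964598271471
20,17.697280852827,0.903596366516
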
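material,density_g_cm3,energy_kev,mu_photoelectric,mu_incoherent
water,1.000,10,4.94000,0.13500
water,1.000,15,1.37000,0.16000
water,1.000,20,0.54400,0.17700
water,1.000,30,0.14400,0.18700
water,1.000,40,0.05400,0.18800
water,1.000,50,0.02450,0.18600
water,1.000,60,0.01350,0.18200
water,1.000,80,0.00580,0.17200
water,1.000,100,0.00280,0.16300
water,1.000,150,0.00070,0.14700
water,1.000,200,0.00026,0.13500
soft_tissue,1.060,10,4.94000,0.13500
soft_tissue,1.060,15,1.37000,0.16000
soft_tissue,1.060,20,0.54400,0.17700
soft_tissue,1.060,30,0.14400,0.18700
soft_tissue,1.060,40,0.05400,0.18800
soft_tissue,1.060,50,0.02450,0.18600
soft_tissue,1.060,60,0.01350,0.18200
soft_tissue,1.060,80,0.00580,0.17200
soft_tissue,1.060,100,0.00280,0.16300
soft_tissue,1.060,150,0.00070,0.14700
soft_tissue,1.060,200,0.00026,0.13500
brain,1.040,10,4.94000,0.13500
brain,1.040,15,1.37000,0.16000
brain,1.040,20,0.54400,0.17700
brain,1.040,30,0.14400,0.18700
brain,1.040,40,0.05400,0.18800
brain,1.040,50,0.02450,0.18600
brain,1.040,60,0.01350,0.18200
brain,1.040,80,0.00580,0.17200
brain,1.040,100,0.00280,0.16300
brain,1.040,150,0.00070,0.14700
brain,1.040,200,0.00026,0.13500
lung,0.260,10,4.94000,0.13500
lung,0.260,15,1.37000,0.16000
lung,0.260,20,0.54400,0.17700
lung,0.260,30,0.14400,0.18700
lung,0.260,40,0.05400,0.18800
lung,0.260,50,0.02450,0.18600
lung,0.260,60,0.01350,0.18200
lung,0.260,80,0.00580,0.17200
lung,0.260,100,0.00280,0.16300
lung,0.260,150,0.00070,0.14700
lung,0.260,200,0.00026,0.13500
bone,1.920,10,27.00000,0.12150
bone,1.920,15,8.50000,0.14400
bone,1.920,20,3.70000,0.15900
bone,1.920,30,1.14000,0.16800
bone,1.920,40,0.48000,0.16900
bone,1.920,50,0.26000,0.16700
bone,1.920,60,0.15500,0.16400
bone,1.920,80,0.06500,0.15500
bone,1.920,100,0.03200,0.14700
bone,1.920,150,0.00950,0.13200
bone,1.920,200,0.00400,0.12150
air,0.0012,10,5.19000,0.12180
air,0.0012,15,1.44000,0.14400
air,0.0012,20,0.57100,0.16000
air,0.0012,30,0.15100,0.16900
air,0.0012,40,0.05670,0.17000
air,0.0012,50,0.02570,0.16800
air,0.0012,60,0.01420,0.16400
air,0.0012,80,0.00610,0.15500
air,0.0012,100,0.00290,0.14700
air,0.0012,150,0.00074,0.13300
air,0.0012,200,0.00027,0.12200
pmma,1.190,10,3.46000,0.13120
pmma,1.190,15,0.95900,0.15550
pmma,1.190,20,0.38100,0.17200
pmma,1.190,30,0.10100,0.18200
pmma,1.190,40,0.03780,0.18300
pmma,1.190,50,0.01720,0.18100
pmma,1.190,60,0.00945,0.17700
pmma,1.190,80,0.00406,0.16700
pmma,1.190,100,0.00196,0.15800
pmma,1.190,150,0.00049,0.14300
pmma,1.190,200,0.00018,0.13100
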
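reach_id,downstream_id,length_m,slope_pct,maf_cms,t_aug_c,w95_days,cfm_day,intermittent,easting_m,northing_m,rt_range,rt_source
R01,,2000,1.0,4.5,14.2,4.1,212,0,1431000,1781000,1,0
R02,R01,1500,1.5,3.2,13.1,3.6,208,0,1430200,1782600,1,0
R03,R02,1200,2.5,1.8,12.0,2.9,204,0,1429600,1783900,0,0
R04,R03,1000,3.5,0.9,11.2,2.5,201,0,1429200,1784800,0,0
R05,R02,1300,3.0,1.0,11.5,2.6,202,0,1431400,1783800,1,1
R06,R05,900,5.0,0.45,10.4,2.0,198,0,1431900,1784500,1,0
R07,R03,1100,4.0,0.8,10.9,2.3,200,0,1428700,1784700,0,0
R08,R07,800,6.0,0.5,10.1,1.8,196,0,1428300,1785300,0,0
R09,R08,1400,7.5,0.3,9.5,1.4,193,0,1427800,1786500,0,0
R10,R04,1000,6.5,0.4,10.2,2.1,199,0,1429000,1785700,0,0
R11,R06,1300,9.0,0.15,8.9,1.1,190,0,1432300,1785600,1,0
R12,R09,1000,9.5,0.1,8.2,0.8,188,0,1427300,1787400,0,0
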
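site_id,reach_id,n_fish,prta_pct,pfrt_pct,ycti
S01,R04,25,0.5,4.0,0
S02,R06,30,12.0,28.0,0
S03,R08,22,3.2,9.1,1
S04,R10,18,0.0,0.0,0
S05,R12,24,55.0,80.0,0
S06,R03,28,22.0,40.0,0
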
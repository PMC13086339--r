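"cage_id","replicate_index","date","temperature_C","boat_count","diet_level","planned_pellets","delivered_pellets"
"C1",1,2021-08-01,27.6,51,60,15,10
"C1",2,2021-09-10,26.15,7,60,15,3
"C1",3,2021-10-19,23.25,0,60,15,4
"C1",4,2021-11-28,21.8,0,60,15,10
"C2",1,2021-08-01,27.6,44,75,15,9
"C2",2,2021-09-10,26.15,10,75,15,4
"C2",3,2021-10-19,23.25,0,75,15,2
"C2",4,2021-11-28,21.8,0,75,15,3
"C3",1,2021-08-01,27.6,35,90,15,4
"C3",2,2021-09-10,26.15,15,90,15,7
"C3",3,2021-10-19,23.25,1,90,15,4
"C3",4,2021-11-28,21.8,0,90,15,9
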
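"fish_id","cage_id","fish_index","total_length_cm"
"C1-F1","C1",1,61.6870670308693
"C1-F2","C1",2,55.4929658515325
"C1-F3","C1",3,58.4620109162795
"C1-F4","C1",4,59.3251603358753
"C1-F5","C1",5,58.5936586340512
"C1-F6","C1",6,56.9604015485072
"C1-F7","C1",7,62.1368703918046
"C1-F8","C1",8,56.9970910770781
"C2-F1","C2",1,63.7589558844065
"C2-F2","C2",2,57.0993148830322
"C2-F3","C2",3,61.4755828935152
"C2-F4","C2",4,64.6172652566435
"C2-F5","C2",5,52.8556457564405
"C2-F6","C2",6,56.4078759461844
"C2-F7","C2",7,56.8733717235403
"C2-F8","C2",8,59.3350412738242
"C3-F1","C3",1,56.3903906514686
"C3-F2","C3",2,48.7993426531047
"C3-F3","C3",3,49.4905058285583
"C3-F4","C3",4,61.5243627063366
"C3-F5","C3",5,56.3187564989489
"C3-F6","C3",6,51.599813011264
"C3-F7","C3",7,56.7498644615692
"C3-F8","C3",8,61.1869590373523
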
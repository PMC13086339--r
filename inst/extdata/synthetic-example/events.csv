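"cage_id","replicate_index","pellet_index","outcome"
"C1",1,1,"7"
"C1",1,2,"4"
"C1",1,3,"8"
"C1",1,4,"7"
"C1",1,5,"2"
"C1",1,6,"6"
"C1",1,7,"8"
"C1",1,8,"2"
"C1",1,9,"4"
"C1",1,10,"4"
"C1",2,1,"4"
"C1",2,2,"8"
"C1",2,3,"3"
"C1",3,1,"5"
"C1",3,2,"5"
"C1",3,3,"4"
"C1",3,4,"6"
"C1",4,1,"4"
"C1",4,2,"6"
"C1",4,3,"7"
"C1",4,4,"4"
"C1",4,5,"4"
"C1",4,6,"8"
"C1",4,7,"6"
"C1",4,8,"6"
"C1",4,9,"6"
"C1",4,10,"6"
"C2",1,1,"2"
"C2",1,2,"8"
"C2",1,3,"6"
"C2",1,4,"4"
"C2",1,5,"4"
"C2",1,6,"5"
"C2",1,7,"8"
"C2",1,8,"1"
"C2",1,9,"3"
"C2",2,1,"4"
"C2",2,2,"4"
"C2",2,3,"8"
"C2",2,4,"4"
"C2",3,1,"2"
"C2",3,2,"3"
"C2",4,1,"3"
"C2",4,2,"4"
"C2",4,3,"2"
"C3",1,1,"NC"
"C3",1,2,"NC"
"C3",1,3,"NC"
"C3",1,4,"5"
"C3",2,1,"5"
"C3",2,2,"6"
"C3",2,3,"6"
"C3",2,4,"3"
"C3",2,5,"8"
"C3",2,6,"2"
"C3",2,7,"8"
"C3",3,1,"NC"
"C3",3,2,"4"
"C3",3,3,"3"
"C3",3,4,"4"
"C3",4,1,"NC"
"C3",4,2,"NC"
"C3",4,3,"4"
"C3",4,4,"8"
"C3",4,5,"5"
"C3",4,6,"NC"
"C3",4,7,"5"
"C3",4,8,"6"
"C3",4,9,"4"
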
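"source_id","canonical_name","canonical_id","model_tag"
1,"air/free space",1,"debye4"
2,"skin (dry)",2,"debye4"
3,"skin (wet)",3,"debye4"
4,"fat",4,"debye4"
5,"bone, cortical",5,"debye4"
6,"bone, cancellous",6,"debye4"
7,"white matter (WM)",7,"debye4"
8,"grey matter (GM)",8,"debye4"
9,"blood",9,"debye4"
10,"cerebrospinal fluid (CSF)",10,"debye4"
11,"dura",11,"debye4"
12,"bone marrow",12,"debye4"
13,"cerebellum",13,"debye4"
14,"spinal cord (nerve)",14,"debye4"
15,"eye tissue (sclera)",15,"debye4"
16,"cartilage",16,"debye4"
17,"muscle, parallel",17,"debye4"
18,"stomach",18,"colecole4"
19,"tongue",19,"colecole4"
20,"trachea",20,"colecole4"
21,"eye lens (nucleus)",21,"colecole4"
22,"skin (dry)",2,"debye4"
23,"skin (wet)",3,"debye4"
24,"fat",4,"debye4"
25,"bone, cortical",5,"debye4"
26,"bone, cancellous",6,"debye4"
27,"white matter (WM)",7,"debye4"
28,"grey matter (GM)",8,"debye4"
29,"blood",9,"debye4"
30,"cerebrospinal fluid (CSF)",10,"debye4"
31,"dura",11,"debye4"
32,"bone marrow",12,"debye4"
33,"cerebellum",13,"debye4"
34,"spinal cord (nerve)",14,"debye4"
35,"eye tissue (sclera)",15,"debye4"
36,"cartilage",16,"debye4"
37,"muscle, parallel",17,"debye4"
38,"skin (dry)",2,"debye4"
39,"skin (wet)",3,"debye4"
40,"fat",4,"debye4"
41,"bone, cortical",5,"debye4"
42,"bone, cancellous",6,"debye4"
43,"white matter (WM)",7,"debye4"
44,"grey matter (GM)",8,"debye4"
45,"blood",9,"debye4"
46,"cerebrospinal fluid (CSF)",10,"debye4"
47,"dura",11,"debye4"
48,"bone marrow",12,"debye4"
49,"cerebellum",13,"debye4"
50,"spinal cord (nerve)",14,"debye4"
51,"eye tissue (sclera)",15,"debye4"
52,"cartilage",16,"debye4"
53,"muscle, parallel",17,"debye4"
54,"skin (dry)",2,"debye4"
55,"skin (wet)",3,"debye4"
56,"fat",4,"debye4"
57,"bone, cortical",5,"debye4"
58,"bone, cancellous",6,"debye4"
59,"white matter (WM)",7,"debye4"
60,"grey matter (GM)",8,"debye4"
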
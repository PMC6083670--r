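"tissue","model_tag","eps_inf","deps1","deps2","deps3","deps4","tau1","tau2","tau3","tau4","alpha1","alpha2","alpha3","alpha4","sigma_static"
"air/free space","debye4",1,0,0,0,0,1e-12,1e-12,1e-12,1e-12,0,0,0,0,0
"skin (dry)","debye4",4,35.701271807025,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,0.569157258453226
"skin (wet)","debye4",4,43.8278407001408,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,0.769435845775708
"fat","debye4",2.5,2.08364054890872,1,5,30,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,0.0381530345652908
"bone, cortical","debye4",2.5,10.140998494627,1,5,30,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,0.143043868237318
"bone, cancellous","debye4",4,14.6923388773772,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,0.2553844840561
"white matter (WM)","debye4",4,33.9032917605032,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,0.616171049490336
"grey matter (GM)","debye4",4,45.8394719321069,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,0.923466859485653
"blood","debye4",4,51.6789700837587,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,1.7024591120487
"cerebrospinal fluid (CSF)","debye4",4,64.2974297686924,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,2.23556260368226
"dura","debye4",4,44.072285741891,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,0.856186216277385
"bone marrow","debye4",2.5,2.61245230931389,1,5,30,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,0.0414313494134002
"cerebellum","debye4",4,45.5189951539403,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,0.929649652365071
"spinal cord (nerve)","debye4",4,29.1926341914766,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,0.515117028205859
"eye tissue (sclera)","debye4",4,50.6892535359746,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,1.0584942348472
"cartilage","debye4",4,36.32968714825,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,0.734630123120033
"muscle, parallel","debye4",4,56.4283456610395,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0,0,0,0,1.08989439841879
"stomach","colecole4",4,61.601411028174,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0.1,0.1,0.2,0,0.954104587904078
"tongue","colecole4",4,51.6566591801815,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0.1,0.1,0.2,0,0.736842686852534
"trachea","colecole4",4,38.1955590769485,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0.1,0.1,0.2,0,0.617154919905626
"eye lens (nucleus)","colecole4",4,31.9809915949121,3,25,200,8.8e-12,1e-09,1.5e-07,1e-05,0.1,0.1,0.2,0,0.351175171140576
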
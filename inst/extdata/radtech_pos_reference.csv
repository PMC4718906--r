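patient_id,time_years,nthi,ppv
42F,0.0,0.748,1.0
32F,0.3,0.743,1.0
41F,-0.8,0.718,1.0
55F,-0.4,0.697,1.0
84M,1.0,0.659,0.50
25M,1.5,0.655,0.50
43M,1.4,0.642,0.35
90M,2.4,0.641,0.38
30F,2.7,0.637,0.38
109F,1.5,0.621,0.32
111F,2.6,0.619,0.33
104F,0.2,0.599,0.27
103M,-0.1,0.581,0.26
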
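lys_a,lys_b,band,condition,mean_pct,sd_pct
53,347,5,with_peptides,4.1,0.4
53,347,4,with_peptides,3.2,1.9
53,347,3,with_peptides,3.7,1.0
53,347,2,with_peptides,4.9,1.0
53,347,1,with_peptides,0.0,0.0
53,349,5,with_peptides,1.4,0.2
53,349,4,with_peptides,1.0,0.4
53,349,3,with_peptides,1.4,0.3
53,349,2,with_peptides,1.5,0.8
53,349,1,with_peptides,0.0,0.0
53,351,5,with_peptides,4.0,1.1
53,351,4,with_peptides,2.4,2.4
53,351,3,with_peptides,3.2,0.8
53,351,2,with_peptides,3.4,0.3
53,351,1,with_peptides,0.0,0.0
121,121,5,with_peptides,3.7,0.9
121,121,4,with_peptides,2.9,1.4
121,121,3,with_peptides,1.5,0.0
121,121,2,with_peptides,0.8,0.3
121,121,1,with_peptides,0.0,0.0
351,265,5,with_peptides,1.2,0.1
351,265,4,with_peptides,0.8,0.6
351,265,3,with_peptides,1.0,0.5
351,265,2,with_peptides,0.4,0.3
351,265,1,with_peptides,0.0,0.0
53,265,5,with_peptides,0.5,0.1
53,265,4,with_peptides,0.4,0.1
53,265,3,with_peptides,0.2,0.0
53,265,2,with_peptides,0.2,0.0
53,265,1,with_peptides,0.0,0.0
53,347,5,without_peptides,3.3,0.3
53,347,4,without_peptides,4.3,1.9
53,347,3,without_peptides,4.4,2.1
53,347,2,without_peptides,3.4,2.5
53,347,1,without_peptides,0.0,0.0
53,349,5,without_peptides,1.6,0.5
53,349,4,without_peptides,1.4,0.5
53,349,3,without_peptides,1.6,0.9
53,349,2,without_peptides,1.6,0.5
53,349,1,without_peptides,0.0,0.0
53,351,5,without_peptides,2.3,0.4
53,351,4,without_peptides,3.2,1.0
53,351,3,without_peptides,2.6,1.7
53,351,2,without_peptides,2.1,2.3
53,351,1,without_peptides,0.0,0.0
121,121,5,without_peptides,2.6,0.2
121,121,4,without_peptides,2.1,0.8
121,121,3,without_peptides,2.1,1.5
121,121,2,without_peptides,0.3,0.1
121,121,1,without_peptides,0.0,0.0
351,265,5,without_peptides,0.6,0.3
351,265,4,without_peptides,0.9,0.2
351,265,3,without_peptides,0.9,0.4
351,265,2,without_peptides,0.4,0.3
351,265,1,without_peptides,0.0,0.0
53,265,5,without_peptides,0.3,0.1
53,265,4,without_peptides,0.4,0.3
53,265,3,without_peptides,0.3,0.1
53,265,2,without_peptides,0.1,0.1
53,265,1,without_peptides,0.0,0.0
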
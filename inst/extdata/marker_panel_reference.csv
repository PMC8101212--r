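locus,n_alleles,hwe_dev
Hi_1-1,29,4
Hi_1-2,36,3
Hi_1-3,31,3
Hi_1-4,30,7
Hi_1-5,17,5
Hi_2-1,12,0
Hi_2-2,25,8
Hi_2-3,19,4
Hi_2-4,31,3
Hi_2-5,8,2
Hi_3-1,30,2
Hi_3-2,28,6
Hi_3-3,24,13
Hi_3-4,32,11
Hi_3-5,16,7
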
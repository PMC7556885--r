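sample,q,tau,n_published,alpha_published
h2.0,0.9,16.693,2.31,0.233
h2.0,1.1,12.465,2.31,0.233
h2.0,1.3,7.485,2.31,0.233
h4.0,0.9,8.953,2.15,0.169
h4.0,1.1,6.344,2.15,0.169
h4.0,1.3,4.017,2.15,0.169
ecoli,0.9,9.999,2.29,0.214
ecoli,1.1,7.370,2.29,0.214
ecoli,1.3,3.987,2.29,0.214
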
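K,m,block_scheme,policy,favoured,rho,alpha,replicates,seed
3,4,PBD_K,I,1,0.25,0.05,500,11
3,4,PBD_N,II,2;3,1,0.05,500,12
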
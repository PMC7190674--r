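rbp_name	motif
RBP_A	TGCATG
RBP_B	GGGAGG
RBP_C	TTTCTT
RBP_D	ACGTAC
RBP_E	GTAAGT
RBP_F	YGCY
RBP_G	TTAGGG
RBP_H	CCWCC
RBP_I	GAAGAA
RBP_J	AKTAGG
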
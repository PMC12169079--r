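cdr3_aa,v_call,j_call,epitope,antigen,source_id
CASSVDRGSYEQYF,TRBV7-9*01,TRBJ2-7*01,YLQPRTFLL,SARS-CoV-2 spike,SYN0001
CASSPDIEAFF,TRBV2*01,TRBJ1-1*01,YLQPRTFLL,SARS-CoV-2 spike,SYN0002
CASSLEGYTEAFF,TRBV20-1*01,TRBJ1-1*01,YLQPRTFLL,SARS-CoV-2 spike,SYN0003
CASSQGRLYNEQFF,TRBV4-1*01,TRBJ2-1*01,YLQPRTFLL,SARS-CoV-2 spike,SYN0004
CASSIRSSYEQYF,TRBV19*01,TRBJ2-7*01,YLQPRTFLL,SARS-CoV-2 spike,SYN0005
CASRPGLAGGRPEQYF,TRBV28*01,TRBJ2-7*01,YLQPRTFLL,SARS-CoV-2 spike,SYN0006
CASSFSGNTIYF,TRBV12-3*01,TRBJ1-3*01,YLQPRTFLL,SARS-CoV-2 spike,SYN0007
CASSAGQGVFNEQFF,TRBV9*01,TRBJ2-1*01,YLQPRTFLL,SARS-CoV-2 spike,SYN0008
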
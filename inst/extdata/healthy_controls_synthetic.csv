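donor_id,n_cmc_ml
H01,0
H02,0
H03,0
H04,0
H05,1
H06,1
H07,1
H08,2
H09,2
H10,3
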
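patient_id,survival_months,alive_at_analysis,n_cmc_slide,cv_percent,n_cmc_ml,braf_status,site,marker,sex
1,5.5,TRUE,4,50,21,positive,cutaneous,MelanA,female
2,4.6,TRUE,10,32,27,positive,cutaneous,MelanA,female
3,31.9,TRUE,79,11,78,positive,cutaneous,S100B,female
4,3.0,FALSE,47,15,125,positive,cutaneous,MelanA,male
5,2.0,FALSE,31,18,165,positive,cutaneous,S100B,male
6,27.8,FALSE,101,10,287,negative,cutaneous,MelanA,female
7,0.5,FALSE,75,12,400,unknown,uveal,MelanA,female
8,33.2,TRUE,42,15,467,unknown,mucosal,S100B,male
9,28.9,TRUE,304,5.7,1013,positive,cutaneous,S100B,female
10,4.5,FALSE,1646,2.5,1568,unknown,mucosal,MelanA,male
11,1.0,FALSE,2134,2.2,28483,positive,cutaneous,MelanA,male
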
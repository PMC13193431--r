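species,size_class,region,model,sex,dw0_mm,dwinf_mm,k,t0,age_max,n,source,excluded
Dasyatis hypostigma,medium,Brazilian Meridional Margin,logistic,male,217.0,401.7,0.45,-0.36,10,201,this_study,FALSE
Dasyatis hypostigma,medium,Brazilian Meridional Margin,logistic,female,225.8,512.2,0.29,0.82,11,71,this_study,FALSE
Dasyatis hypostigma,medium,Uruguay-Argentina,logistic,male,223.5,468.2,0.3,0.3,7,22,Ruocco,FALSE
Dasyatis hypostigma,medium,Uruguay-Argentina,logistic,female,242.1,568.9,0.2,1.5,13,29,Ruocco,FALSE
Dasyatis pastinaca,large,Mediterranean Sea,vbgm3,pooled,162.6,1215.0,0.089,-1.615,10,256,Ismen,FALSE
Dasyatis pastinaca,large,Mediterranean Sea,vbgm3,pooled,106.2,1044.3,0.075,-1.43,13,384,Girgin & Basusta,FALSE
Dasyatis pastinaca,large,Mediterranean Sea,vbgm3,male,158.4,1145.4,0.041,-3.63,13,175,Girgin & Basusta,FALSE
Dasyatis pastinaca,large,Mediterranean Sea,vbgm3,female,106.5,1270.6,0.058,-1.51,13,209,Girgin & Basusta,FALSE
Dasyatis pastinaca,medium,Aegean Sea,vbgm3,pooled,7.4,582.8,0.06,-0.213,13,72,Yeldan & Gundogdu,TRUE
Dasyatis marmorata,medium,Aegean Sea,vbgm3,pooled,31.8,460.9,0.36,-0.162,13,143,Yeldan & Gundogdu,TRUE
Bathytoshia lata,large,Hawai'i,logistic,male,405.0,1166.0,0.14,4.52,25,88,Dale & Holland,FALSE
Bathytoshia lata,large,Hawai'i,logistic,female,406.0,1441.0,0.12,7.61,28,115,Dale & Holland,FALSE
Hypanus dipterurus,medium,Pacific Mexico,vbgm3,male,313.0,622.0,0.1,-6.8,19,148,Smith et al.,FALSE
Hypanus dipterurus,large,Pacific Mexico,vbgm3,female,314.0,924.0,0.05,-7.61,28,191,Smith et al.,FALSE
Dasyatis chrysonota,medium,Eastern South Africa,vbgm3,male,251.1,531.8,0.175,-3.65,5,105,Cowley,FALSE
Dasyatis chrysonota,large,Eastern South Africa,vbgm3,female,245.9,913.4,0.07,-4.48,7,165,Cowley,FALSE
Hypanus guttatus,medium,Ceara NE Brazil,vbgm2,male,145.0,602.2,0.219,,9,95,Gianeti et al.,FALSE
Hypanus guttatus,large,Ceara NE Brazil,vbgm2,female,145.0,986.1,0.112,,14,101,Gianeti et al.,FALSE
Hypanus guttatus,medium,Pernambuco NE Brazil,vbgm3,pooled,168.7,660.1,0.18,-1.64,13,203,Vieira,FALSE
Hypanus guttatus,medium,Maranhao NE Brazil,vbgm3,pooled,267.3,602.8,0.2,-2.93,15,59,Vieira,FALSE
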
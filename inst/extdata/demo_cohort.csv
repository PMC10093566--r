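patient_id,node_id,station,short_axis_mm,suvmax,suvmean,suvpeak,histology,primary_suvmax,liver_suvmax,brainstem_suvmax,lung_suvmax,glucose_mmol_per_l,uptake_time_min,injected_activity_mbq,body_weight_kg,age_years,sex,histology_subtype
P1,P1_N1,7,18.5,8.2,5.8,7.4,malignant,12.4,3.6,6.8,0.9,5.6,55,236,78,66,m,AC
P1,P1_N2,4,7.2,2.1,1.5,1.9,benign,12.4,3.6,6.8,0.9,5.6,55,236,78,66,m,AC
P1,P1_N3,10,9.8,3.3,2.2,2.9,benign,12.4,3.6,6.8,0.9,5.6,55,236,78,66,m,AC
P2,P2_N1,2,22.0,11.5,8.1,10.3,malignant,16.0,3.2,6.1,1.1,6.8,60,231,64,71,f,SCC
P2,P2_N2,7,10.4,4.0,2.8,3.5,benign,16.0,3.2,6.1,1.1,6.8,60,231,64,71,f,SCC
P2,P2_N3,11,6.1,1.8,1.2,1.6,benign,16.0,3.2,6.1,1.1,6.8,60,231,64,71,f,SCC
P3,P3_N1,5,14.9,6.4,4.5,5.8,malignant,9.8,3.9,7.2,0.8,4.9,48,240,92,58,m,AC
P3,P3_N2,12,5.5,2.6,1.8,2.3,benign,9.8,3.9,7.2,0.8,4.9,48,240,92,58,m,AC
P4,P4_N1,6,25.3,13.2,9.6,12.1,malignant,18.5,3.1,6.5,1.3,7.4,67,228,59,77,f,SCLC
P4,P4_N2,4,8.0,2.9,2.0,2.5,benign,18.5,3.1,6.5,1.3,7.4,67,228,59,77,f,SCLC
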
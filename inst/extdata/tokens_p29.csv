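token_id,participant_id,group,item_id,condition,dur_s1,dur_s2,f0_l,f0_h,disfluent,labeling_error
P29_I01,P29,SZ,I01,given,0.2,0.2,180,185,false,false
P29_I02,P29,SZ,I02,given,0.2,0.2,180,185,false,false
P29_I03,P29,SZ,I03,given,0.2,0.2,180,185,false,false
P29_I04,P29,SZ,I04,given,0.2,0.26,180,220,false,false
P29_I05,P29,SZ,I05,given,0.2,0.26,180,220,false,false
P29_I06,P29,SZ,I06,given,0.2,0.26,180,220,false,false
P29_I07,P29,SZ,I07,given,0.2,0.26,180,220,false,false
P29_I08,P29,SZ,I08,given,0.2,0.26,180,220,false,false
P29_I09,P29,SZ,I09,given,0.2,0.26,180,220,false,false
P29_I10,P29,SZ,I10,contrastive,0.2,0.26,180,220,false,false
P29_I11,P29,SZ,I11,contrastive,0.2,0.26,180,220,false,false
P29_I12,P29,SZ,I12,contrastive,0.2,0.26,180,220,false,false
P29_I13,P29,SZ,I13,contrastive,0.2,0.26,180,220,false,false
P29_I14,P29,SZ,I14,contrastive,0.2,0.26,180,220,false,false
P29_I15,P29,SZ,I15,contrastive,0.2,0.26,180,220,false,false
P29_I16,P29,SZ,I16,contrastive,0.2,0.2,180,185,false,false
P29_I17,P29,SZ,I17,contrastive,0.2,0.2,180,185,false,false
P29_I18,P29,SZ,I18,contrastive,0.2,0.2,180,185,false,false
P30_I01,P30,SZ,I01,given,0.2,0.2,180,185,false,false
P30_I02,P30,SZ,I02,given,0.2,0.2,180,185,false,false
P30_I03,P30,SZ,I03,given,0.2,0.2,180,185,false,false
P30_I04,P30,SZ,I04,given,0.2,0.26,180,220,false,false
P30_I05,P30,SZ,I05,given,0.2,0.26,180,220,false,false
P30_I06,P30,SZ,I06,given,0.2,0.26,180,220,false,false
P30_I07,P30,SZ,I07,given,0.2,0.26,180,220,false,false
P30_I08,P30,SZ,I08,given,0.2,0.26,180,220,false,false
P30_I09,P30,SZ,I09,given,0.2,0.26,180,220,false,false
P30_I10,P30,SZ,I10,contrastive,0.2,0.26,180,220,false,false
P30_I11,P30,SZ,I11,contrastive,0.2,0.26,180,220,false,false
P30_I12,P30,SZ,I12,contrastive,0.2,0.26,180,220,false,false
P30_I13,P30,SZ,I13,contrastive,0.2,0.26,180,220,false,false
P30_I14,P30,SZ,I14,contrastive,0.2,0.26,180,220,false,false
P30_I15,P30,SZ,I15,contrastive,0.2,0.26,180,220,false,false
P30_I16,P30,SZ,I16,contrastive,0.2,0.2,180,185,false,false
P30_I17,P30,SZ,I17,contrastive,0.2,0.2,180,185,false,false
P30_I18,P30,SZ,I18,contrastive,0.2,0.2,180,185,false,false
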
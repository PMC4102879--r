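token_id,participant_id,group,item_id,condition,disfluent,labeling_error,hinting_score
T1,P01,HC,I01,contrastive,false,false,18
T2,P02,HC,I01,given,false,false,19
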
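participant_id,group,hinting_score,total_time,speaking_turns
P29,SZ,13,210.5,31
P30,SZ,15,198.2,29
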
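complaint_id,timestamp,building_id,descriptor,police_action
C001,2020-03-28T17:45:00,B001,social distancing,TRUE
C002,2020-03-28T13:10:00,B002,social distancing,FALSE
C003,bad-stamp,B001,social distancing,FALSE
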
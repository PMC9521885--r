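poi_id,timestamp,visits,open
P001,2020-03-28T12:00:00,3,TRUE
P002,2020-03-28T12:00:00,1,TRUE
P003,2020-03-28T12:00:00,5,TRUE
P001,2020-03-28T13:00:00,2,TRUE
P002,2020-03-28T13:00:00,2,TRUE
P003,2020-03-28T13:00:00,-4,TRUE
P001,not-a-time,1,TRUE
P003,2020-03-28T14:00:00,0,FALSE
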
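poi_id,building_id,zip,poi_type,floor_area
P001,B001,Z001,store,5000
P002,B001,Z001,food_and_drink,5000
P003,B002,Z002,grocery,8000
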
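"zip","SDS_z","n_units"
"Z001",95.1626898775811,5
"Z002",77.5909657582428,5
"Z003",70.8289373580994,5
"Z004",0,1
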
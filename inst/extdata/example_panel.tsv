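stock_id	dp_name	interval
BSC75	Dp(1;Y)BSC75	2C1-3E4
BSC159	Dp(1;Y)BSC159	4A5-4D7
BSC289	Dp(1;Y)BSC289	5E1-6C7
BSC176	Dp(1;Y)BSC176	7B2-7D18
BSC126	Dp(1;Y)BSC126	11C2-11D1
BSC327	Dp(1;Y)BSC327	11D5-11E8
BSC186	Dp(1;Y)BSC186	12C1-12F4
BSC269	Dp(1;Y)BSC269	12E9-13C5
BSC11	Dp(1;Y)BSC11	16F6-18A7
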
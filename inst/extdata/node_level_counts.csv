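location,malignant,benign
Level I right,5,9
Level I left,0,5
Level II right,74,100
Level II left,60,122
Level III right,285,272
Level III left,263,348
Level IV right,310,184
Level IV left,273,328
Level V right,10,44
Level V left,11,33
Level VI right,102,35
Level VI left,105,49
Level VII,26,6
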
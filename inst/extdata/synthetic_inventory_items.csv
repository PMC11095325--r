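"item_id","scale","key"
"ext1","extraversion",1
"ext2","extraversion",-1
"ext3","extraversion",1
"ext4","extraversion",-1
"agr1","agreeableness",1
"agr2","agreeableness",-1
"agr3","agreeableness",1
"agr4","agreeableness",-1
"con1","conscientiousness",1
"con2","conscientiousness",-1
"con3","conscientiousness",1
"con4","conscientiousness",-1
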
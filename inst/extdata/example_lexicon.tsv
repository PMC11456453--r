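他	5000
泡	200
茶	500
很	8000
好喝	50
喝	900
完	300
了	9000
大家	420
聊天	150
被	1200
把	1500
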
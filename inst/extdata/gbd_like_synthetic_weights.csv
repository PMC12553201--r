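"disease","weight"
"diabetes",0.049
"diabetes",0.133
"diabetes",0.211
"kidney",0.104
"kidney",0.376
"kidney",0.569
"respiratory",0.019
"respiratory",0.225
"respiratory",0.408
"heart",0.041
"heart",0.072
"heart",0.179
"heart",0.405
"tumor",0.049
"tumor",0.288
"tumor",0.451
"tumor",0.54
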
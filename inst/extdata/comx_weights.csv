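"","A","B","C","D","E"
"A",1,0.3,0.4,-0.2,0.1
"B",-0.12,1,-1,-0.3,1.05
"C",0.445,-1.5,1,-2,-0.2
"D",0.2,-0.4,0.3,1,-0.2
"E",0,0,0,0,1
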
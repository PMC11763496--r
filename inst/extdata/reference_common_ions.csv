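medium,period_days,polarity,mz,abundance_F0728,abundance_F0891
MEA,7,pos,211,28.4,69.4
MEA,15,pos,213,10.8,26.7
MEA,15,neg,213,16.7,30.2
MEA,22,neg,249,31.2,24.4
MEA,30,pos,213,25.5,28.3
PDA,7,pos,180,37.9,27.1
PDA,15,pos,213,47.5,34.3
PDA,15,neg,249,18.9,100
PDA,22,pos,213,21.2,51.9
PDA,30,pos,213,96.6,28.8
PDA,30,neg,235,20.0,69.0
PDA,30,neg,249,32.3,100
SDA,7,pos,211,24.4,100
SDA,7,neg,193,13.6,10.6
SDA,15,pos,211,23.6,100
SDA,22,pos,211,30.4,100
SDA,30,pos,211,27.3,100
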
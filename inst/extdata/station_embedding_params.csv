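station,factor,dimension,delay
ST1,Do,5,18
ST1,Chl,8,28
ST1,Turb,6,42
ST1,Bga,5,22
ST1,Tds,6,19
ST1,DoP,5,14
ST1,Temp,5,14
ST1,pH,6,9
ST2,Do,4,22
ST2,Chl,9,18
ST2,Turb,8,22
ST2,Bga,8,22
ST2,Tds,7,35
ST2,DoP,6,15
ST2,Temp,5,15
ST2,pH,6,18
ST3,Do,4,13
ST3,Chl,7,15
ST3,Turb,15,24
ST3,Bga,17,24
ST3,Tds,7,20
ST3,DoP,5,21
ST3,Temp,6,26
ST3,pH,5,18
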
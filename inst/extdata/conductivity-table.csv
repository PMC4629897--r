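"class","targetCv","ratio","cellRegion","sigmaL","sigmaT","achievedCv"
"atrial",63.3,0.35,"RA/PM",2.30784491109238,0.807745718882332,63.4170702779124
"isthmus",75,1,"RA/PM",3.23982630541279,3.23982630541279,74.9405754725659
"pv",76.6,0.5,"PV",3.3918029581862,1.6959014790931,76.5042363719376
"bundle",116,0.15,"CT/BB",7.88479583561472,1.18271937534221,115.969959438569
"cs",99.5,0.5,"LA",5.69130427208328,2.84565213604164,98.7247444119136
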
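province	region
Beijing	eastern
Tianjin	eastern
Hebei	eastern
Shanghai	eastern
Jiangsu	eastern
Zhejiang	eastern
Fujian	eastern
Shandong	eastern
Guangdong	eastern
Hainan	eastern
Shanxi	central
Anhui	central
Jiangxi	central
Henan	central
Hubei	central
Hunan	central
Inner Mongolia	western
Guangxi	western
Chongqing	western
Sichuan	western
Guizhou	western
Yunnan	western
Tibet	western
Shaanxi	western
Gansu	western
Qinghai	western
Ningxia	western
Xinjiang	western
Liaoning	northeast
Jilin	northeast
Heilongjiang	northeast
Overseas	overseas
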
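"","SMA","PreMA_L","PreMA_R","BA_L","BA_R","AG_L","AG_R","WA_L","WA_R","SMG_L","SMG_R"
"SMA",1,0.212765957446809,0.361702127659574,0.764,0.293617021276596,0.336170212765957,0.234042553191489,0.302127659574468,0.246808510638298,0.323404255319149,0.348936170212766
"PreMA_L",0.212765957446809,1,0.625,0.2,0.378723404255319,0.285106382978723,0.259574468085106,0.374468085106383,0.387234042553191,0.370212765957447,0.263829787234043
"PreMA_R",0.361702127659574,0.625,1,0.340425531914894,0.25531914893617,0.395744680851064,0.357446808510638,0.331914893617021,0.391489361702128,0.276595744680851,0.28936170212766
"BA_L",0.764,0.2,0.340425531914894,1,0.272340425531915,0.238297872340426,0.217021276595745,0.314893617021277,0.280851063829787,0.382978723404255,0.251063829787234
"BA_R",0.293617021276596,0.378723404255319,0.25531914893617,0.272340425531915,1,0.225531914893617,0.34468085106383,0.56,0.56,0.4,0.242553191489362
"AG_L",0.336170212765957,0.285106382978723,0.395744680851064,0.238297872340426,0.225531914893617,1,0.624,0.204255319148936,0.208510638297872,0.297872340425532,0.365957446808511
"AG_R",0.234042553191489,0.259574468085106,0.357446808510638,0.217021276595745,0.34468085106383,0.624,1,0.353191489361702,0.221276595744681,0.319148936170213,0.306382978723404
"WA_L",0.302127659574468,0.374468085106383,0.331914893617021,0.314893617021277,0.56,0.204255319148936,0.353191489361702,1,0.56,0.268085106382979,0.229787234042553
"WA_R",0.246808510638298,0.387234042553191,0.391489361702128,0.280851063829787,0.56,0.208510638297872,0.221276595744681,0.56,1,0.327659574468085,0.31063829787234
"SMG_L",0.323404255319149,0.370212765957447,0.276595744680851,0.382978723404255,0.4,0.297872340425532,0.319148936170213,0.268085106382979,0.327659574468085,1,0.538
"SMG_R",0.348936170212766,0.263829787234043,0.28936170212766,0.251063829787234,0.242553191489362,0.365957446808511,0.306382978723404,0.229787234042553,0.31063829787234,0.538,1
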
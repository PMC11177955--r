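source	target	tract
SMA	BA_L	FAT
SMA	BA_R	FAT
SMA	PreMA_L	SMA-premotor
SMA	PreMA_R	SMA-premotor
BA_L	WA_L	AF/dorsal-II
BA_R	WA_R	AF/dorsal-II
PreMA_L	WA_L	dorsal-I
PreMA_R	WA_R	dorsal-I
BA_L	SMG_L	SLF
BA_R	SMG_R	SLF
PreMA_L	SMG_L	SLF
PreMA_R	SMG_R	SLF
BA_L	AG_L	SLF
BA_R	AG_R	SLF
PreMA_L	AG_L	SLF
PreMA_R	AG_R	SLF
AG_L	WA_L	parietal-temporal
AG_R	WA_R	parietal-temporal
AG_L	SMG_L	parietal-parietal
AG_R	SMG_R	parietal-parietal
BA_L	BA_R	callosal
AG_L	AG_R	callosal
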
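DS0001 0 0 PB_SIRE
DS0002 0 0 PB_SIRE
DS0003 0 0 PB_SIRE
DD0001 0 0 ANCESTOR
DD0002 0 0 ANCESTOR
DD0003 0 0 ANCESTOR
LS0001 0 0 ANCESTOR
LS0002 0 0 ANCESTOR
LS0003 0 0 ANCESTOR
LD0001 0 0 ANCESTOR
LD0002 0 0 ANCESTOR
LD0003 0 0 ANCESTOR
LD0004 0 0 ANCESTOR
LD0005 0 0 ANCESTOR
YS0001 0 0 ANCESTOR
YS0002 0 0 ANCESTOR
YS0003 0 0 ANCESTOR
YD0001 0 0 ANCESTOR
YD0002 0 0 ANCESTOR
YD0003 0 0 ANCESTOR
YD0004 0 0 ANCESTOR
YD0005 0 0 ANCESTOR
PB0001 DS0001 DD0001 PB
PB0002 DS0001 DD0001 PB
PB0003 DS0001 DD0001 PB
PB0004 DS0001 DD0001 PB
PB0005 DS0001 DD0001 PB
PB0006 DS0001 DD0001 PB
PB0007 DS0003 DD0002 PB
PB0008 DS0003 DD0002 PB
PB0009 DS0003 DD0002 PB
PB0010 DS0003 DD0002 PB
PB0011 DS0003 DD0002 PB
PB0012 DS0003 DD0002 PB
PB0013 DS0002 DD0003 PB
PB0014 DS0002 DD0003 PB
PB0015 DS0002 DD0003 PB
PB0016 DS0002 DD0003 PB
PB0017 DS0002 DD0003 PB
PB0018 DS0002 DD0003 PB
F10007 YS0001 LD0004 DAM
F10006 YS0003 LD0003 DAM
F10008 YS0003 LD0003 DAM
F10009 YS0003 LD0002 DAM
F10001 LS0002 YD0002 DAM
F10003 LS0001 YD0002 DAM
F10005 LS0002 YD0003 DAM
F10004 LS0002 YD0004 DAM
F10002 LS0003 YD0005 DAM
CB0025 DS0003 F10007 CB
CB0026 DS0003 F10007 CB
CB0027 DS0003 F10007 CB
CB0028 DS0003 F10007 CB
CB0021 DS0003 F10006 CB
CB0022 DS0003 F10006 CB
CB0023 DS0003 F10006 CB
CB0024 DS0003 F10006 CB
CB0029 DS0002 F10008 CB
CB0030 DS0002 F10008 CB
CB0031 DS0002 F10008 CB
CB0032 DS0002 F10008 CB
CB0033 DS0001 F10009 CB
CB0034 DS0001 F10009 CB
CB0035 DS0001 F10009 CB
CB0036 DS0001 F10009 CB
CB0001 DS0001 F10001 CB
CB0002 DS0001 F10001 CB
CB0003 DS0001 F10001 CB
CB0004 DS0001 F10001 CB
CB0009 DS0001 F10003 CB
CB0010 DS0001 F10003 CB
CB0011 DS0001 F10003 CB
CB0012 DS0001 F10003 CB
CB0017 DS0002 F10005 CB
CB0018 DS0002 F10005 CB
CB0019 DS0002 F10005 CB
CB0020 DS0002 F10005 CB
CB0013 DS0002 F10004 CB
CB0014 DS0002 F10004 CB
CB0015 DS0002 F10004 CB
CB0016 DS0002 F10004 CB
CB0005 DS0003 F10002 CB
CB0006 DS0003 F10002 CB
CB0007 DS0003 F10002 CB
CB0008 DS0003 F10002 CB
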
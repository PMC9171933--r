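id snp00001 snp00002 snp00003 snp00004 snp00005 snp00006 snp00007 snp00008 snp00009 snp00010 snp00011 snp00012 snp00013 snp00014 snp00015 snp00016 snp00017 snp00018 snp00019 snp00020 snp00021 snp00022 snp00023 snp00024 snp00025 snp00026 snp00027 snp00028 snp00029 snp00030 snp00031 snp00032 snp00033 snp00034 snp00035 snp00036 snp00037 snp00038 snp00039 snp00040
DS0001 2 2 0 0 1 2 0 1 0 2 1 0 2 0 0 1 0 0 2 0 0 0 2 2 2 1 1 2 2 1 2 2 0 0 0 1 1 2 1 2
DS0002 2 2 0 0 1 1 1 2 0 2 0 0 2 1 1 0 1 0 1 1 0 0 2 2 2 0 1 2 2 1 2 2 2 0 2 1 2 2 1 2
DS0003 2 2 0 0 2 1 0 1 0 2 2 0 2 0 2 1 1 1 1 1 1 1 2 2 2 1 2 2 2 1 2 0 0 0 1 2 1 1 0 2
DD0001 2 2 0 0 0 0 0 1 0 0 1 0 2 1 2 1 1 0 1 1 0 1 2 2 1 0 2 2 2 1 2 0 1 0 0 1 0 1 1 2
DD0002 2 1 0 0 0 1 0 1 0 1 0 1 2 1 1 0 1 0 1 0 1 1 2 1 2 0 0 1 2 1 1 1 1 0 0 2 1 1 1 0
DD0003 1 2 0 0 0 2 0 2 0 1 0 0 1 0 2 0 1 0 2 0 0 0 2 2 2 0 1 1 2 0 2 2 1 0 1 0 2 0 2 1
LS0001 2 2 0 0 1 2 0 1 0 0 1 0 2 2 1 0 2 0 2 2 1 0 1 2 2 0 2 1 2 1 1 1 0 1 1 2 1 2 1 2
LS0002 2 1 0 0 1 2 1 2 0 0 1 0 2 2 1 0 1 0 2 0 1 1 1 2 2 0 2 1 2 2 2 1 0 0 2 1 0 2 1 2
LS0003 2 2 0 0 1 2 0 1 2 1 1 1 2 0 0 0 2 0 2 1 2 1 2 2 2 0 2 1 2 1 1 1 0 1 0 2 2 2 1 1
LD0001 2 2 0 0 1 1 1 1 0 1 1 1 2 0 1 0 2 0 2 1 2 0 2 2 2 0 2 2 2 0 1 0 1 2 0 1 0 2 0 1
LD0002 2 1 0 0 0 2 1 0 0 1 0 0 2 0 1 1 1 0 2 0 0 2 2 2 2 0 0 1 2 1 2 0 0 0 0 1 0 2 2 1
LD0003 2 2 0 0 0 2 0 1 0 0 0 0 2 1 0 0 2 0 2 2 2 1 2 1 2 0 2 2 2 1 1 1 1 0 1 2 1 2 1 2
LD0004 2 1 0 0 0 2 0 2 1 1 1 0 2 1 1 0 2 0 0 1 2 1 2 2 2 1 2 2 2 0 1 1 0 0 1 1 1 2 1 1
LD0005 2 1 0 0 0 2 1 2 1 1 1 0 2 1 0 1 1 0 2 0 2 1 2 2 2 0 2 1 2 1 1 1 0 1 2 0 0 2 0 2
YS0001 2 0 0 0 2 1 1 1 0 2 0 0 1 0 1 0 0 0 2 0 1 1 2 2 2 0 0 2 1 2 2 1 0 0 0 2 2 2 2 1
YS0002 2 0 0 0 1 1 2 2 0 1 0 1 1 0 2 0 0 0 2 0 1 0 2 2 2 0 1 0 1 1 2 1 1 0 0 2 2 2 0 2
YS0003 2 0 0 1 1 0 2 2 0 2 1 1 1 0 2 0 0 0 2 0 2 0 2 2 2 1 1 0 1 2 2 1 0 0 0 2 1 1 2 1
YD0001 2 0 0 0 0 1 2 2 0 2 0 1 2 0 2 0 0 0 2 0 2 1 2 2 1 0 0 0 1 2 2 0 1 0 1 1 0 2 2 2
YD0002 2 0 0 1 0 0 0 1 0 2 0 1 0 0 0 0 0 0 2 0 2 0 2 2 2 0 1 0 2 1 2 1 2 0 0 2 1 1 2 1
YD0003 2 1 0 1 1 0 1 2 0 1 0 0 1 0 0 0 1 0 2 0 1 1 2 2 2 0 1 2 2 2 1 0 1 0 0 2 2 2 2 2
YD0004 2 0 0 0 2 0 1 2 0 1 0 1 2 0 2 0 1 0 2 1 2 1 2 2 0 0 1 0 2 1 2 0 1 0 1 1 2 2 2 1
YD0005 2 1 0 0 1 1 1 2 0 1 1 0 2 0 2 0 1 0 2 0 2 0 2 2 2 0 1 1 1 1 2 0 2 0 0 2 1 2 2 1
PB0001 2 2 0 0 0 1 0 2 0 1 1 0 2 0 1 1 1 0 1 1 0 1 2 2 1 0 2 2 2 2 2 1 1 0 0 0 0 1 2 2
PB0002 2 2 0 0 1 1 0 1 0 1 0 0 2 1 1 1 1 0 2 0 0 1 2 2 1 1 1 2 2 0 2 1 0 0 0 1 1 1 1 2
PB0003 2 2 0 0 1 1 0 1 0 1 2 0 2 1 1 2 0 0 2 0 0 0 2 2 2 0 2 2 2 1 2 1 0 0 0 0 0 2 2 2
PB0004 2 2 0 0 0 1 0 2 0 1 2 0 2 1 1 1 1 0 1 1 0 1 2 2 1 1 1 2 2 2 2 1 0 0 0 2 0 2 1 2
PB0005 2 2 0 0 1 1 0 0 0 1 1 0 2 0 1 2 0 0 1 0 0 0 2 2 1 1 1 2 2 1 2 1 1 0 0 0 1 1 1 2
PB0006 2 2 0 0 1 1 0 0 0 1 1 0 2 0 1 2 0 0 1 0 0 0 2 2 2 0 2 2 2 0 2 1 0 0 0 2 0 2 0 2
PB0007 2 2 0 0 1 2 0 0 0 1 1 0 2 1 1 1 0 1 1 0 2 1 2 1 2 0 1 2 2 0 2 1 0 0 1 2 1 1 0 1
PB0008 2 2 0 0 1 0 0 1 0 1 1 0 2 1 2 1 2 0 2 1 1 1 2 2 2 0 1 1 2 1 2 0 0 0 0 2 1 1 0 1
PB0009 2 1 0 0 1 1 0 1 0 2 1 1 2 0 2 0 0 1 2 1 2 2 2 2 2 1 1 2 2 1 1 1 0 0 0 2 0 0 0 1
PB0010 2 1 0 0 1 1 0 1 0 1 1 0 2 1 1 0 0 0 2 0 2 1 2 1 2 0 1 1 2 1 2 1 0 0 0 2 2 2 1 1
PB0011 2 2 0 0 1 1 0 1 0 1 1 0 2 0 2 0 1 1 1 1 1 1 2 1 2 0 1 1 2 1 1 1 0 0 0 2 1 2 1 1
PB0012 2 1 0 0 1 0 0 2 0 1 1 1 2 0 1 1 1 1 0 0 1 2 2 1 2 0 1 1 2 2 2 0 1 0 0 2 0 2 1 1
PB0013 1 2 0 0 1 2 0 2 0 1 0 0 2 0 1 0 1 0 1 0 0 0 2 2 2 0 1 2 2 0 2 2 1 0 2 0 2 1 2 2
PB0014 2 2 0 0 0 1 1 2 0 2 0 0 2 1 2 0 0 0 1 1 0 0 2 2 2 0 0 1 2 1 2 2 1 0 2 0 2 1 1 2
PB0015 1 2 0 0 0 1 0 2 0 2 0 0 2 1 1 0 1 0 2 1 0 0 2 2 2 0 1 1 2 0 2 2 2 0 1 0 2 1 1 1
PB0016 1 2 0 0 1 1 1 2 0 1 0 0 1 0 2 0 1 0 1 1 0 0 2 2 2 0 0 1 2 0 2 2 1 0 2 0 2 1 1 2
PB0017 2 2 0 0 1 1 1 2 0 1 0 0 1 0 2 0 0 0 2 0 0 0 2 2 2 0 0 2 2 1 2 2 2 0 2 1 2 1 2 2
PB0018 2 2 0 0 0 2 0 2 0 1 0 0 2 0 2 0 0 0 2 1 0 0 2 2 2 0 1 1 2 0 2 2 1 0 2 1 2 1 1 2
F10007 2 0 0 0 1 2 0 1 0 2 0 0 2 1 1 0 1 0 1 1 2 1 2 2 2 0 1 2 1 1 2 0 0 0 0 2 2 2 1 0
F10006 2 1 0 1 0 1 1 1 0 1 0 0 1 0 1 0 1 0 2 1 2 1 2 1 2 1 2 1 2 2 2 1 1 0 0 2 2 1 1 1
F10008 2 1 0 0 0 1 1 2 0 1 1 1 2 1 1 0 1 0 2 1 2 1 2 1 2 1 1 1 1 1 2 2 0 0 0 2 0 1 2 2
F10009 2 1 0 1 1 1 2 1 0 1 1 0 1 0 2 1 1 0 2 0 1 1 2 2 2 1 1 1 1 1 2 0 0 0 0 1 1 1 2 1
F10001 2 0 0 0 1 1 1 2 0 1 0 1 1 1 1 0 1 0 2 0 2 0 1 2 2 0 2 1 2 1 2 0 1 0 1 1 1 1 1 1
F10003 2 1 0 1 0 1 0 1 0 1 1 0 1 1 0 0 1 0 2 1 2 0 2 2 2 0 1 1 2 2 1 1 1 1 1 2 2 1 1 1
F10005 2 2 0 1 1 1 1 2 0 1 0 0 2 1 0 0 1 0 2 0 1 2 1 2 2 0 1 2 2 2 1 1 1 0 1 2 1 2 1 2
F10004 2 1 0 0 2 1 0 2 0 0 0 0 2 1 1 0 2 0 2 0 1 1 2 2 1 0 2 0 2 2 2 0 0 0 2 0 1 2 1 2
F10002 2 1 0 0 1 2 1 1 1 1 0 0 2 0 1 0 2 0 2 1 2 1 2 2 2 0 1 2 1 1 1 1 1 0 0 2 1 2 1 2
CB0025 2 1 0 0 1 2 0 2 0 2 1 0 2 0 2 1 2 1 0 1 2 1 2 2 2 1 2 2 1 0 2 0 0 0 0 2 1 1 0 1
CB0026 2 1 0 0 1 1 0 1 0 2 1 0 2 0 2 1 0 0 1 2 2 0 2 2 2 0 1 2 2 1 2 0 0 0 1 2 1 2 1 1
CB0027 2 1 0 0 1 2 0 0 0 2 1 0 2 1 2 1 2 0 1 0 1 1 2 2 2 0 2 2 1 1 2 0 0 0 1 2 2 2 1 1
CB0028 2 1 0 0 1 1 0 1 0 2 1 0 2 1 1 1 1 1 1 0 1 2 2 2 2 1 1 2 1 1 2 0 0 0 0 2 1 1 1 1
CB0021 2 1 0 0 1 2 1 2 0 2 1 0 2 0 2 0 1 1 1 1 2 2 2 1 2 1 2 2 2 2 2 0 1 0 1 2 1 2 0 1
CB0022 2 1 0 0 1 1 1 1 0 1 1 0 2 0 1 0 2 1 2 0 2 2 2 1 2 1 2 1 2 1 2 1 1 0 1 2 2 2 0 1
CB0023 2 2 0 0 1 0 1 2 0 2 1 0 1 0 1 0 2 1 2 1 1 2 2 2 2 1 2 1 2 2 2 1 1 0 1 2 1 0 0 1
CB0024 2 2 0 0 1 2 0 0 0 2 1 0 2 0 2 1 2 1 1 2 1 0 2 2 2 2 2 1 2 2 2 1 1 0 0 2 1 2 0 2
CB0029 2 2 0 0 1 1 0 2 0 1 1 1 2 2 1 0 2 0 1 1 1 1 2 1 2 1 1 2 1 0 2 2 1 0 1 2 1 2 2 2
CB0030 2 2 0 0 0 2 1 2 0 1 1 0 2 1 1 0 1 0 1 1 1 0 2 2 2 1 2 1 2 1 2 2 1 0 1 2 1 2 1 2
CB0031 2 1 0 0 1 2 0 2 0 1 0 1 2 2 1 0 0 0 2 2 1 0 2 2 2 0 0 2 1 1 2 2 1 0 1 2 1 2 2 2
CB0032 2 1 0 0 0 2 1 2 0 1 1 0 2 0 1 0 0 0 1 1 1 1 2 1 2 0 0 1 2 1 2 2 1 0 1 2 1 2 1 2
CB0033 2 2 0 1 1 2 1 0 0 2 1 0 2 0 1 1 1 0 2 0 0 0 2 2 2 0 2 2 2 1 2 1 0 0 0 1 0 1 1 1
CB0034 2 2 0 0 1 2 1 0 0 1 1 0 2 0 1 1 0 0 2 0 0 1 2 2 2 0 0 1 2 1 2 1 0 0 0 1 2 1 2 1
CB0035 2 2 0 1 1 1 1 0 0 2 1 0 1 0 1 0 0 0 2 0 0 0 2 2 2 1 1 2 2 1 2 1 0 0 0 2 2 2 2 2
CB0036 2 2 0 0 1 1 1 1 0 1 2 0 2 0 1 1 0 0 2 0 0 1 2 2 2 1 0 1 2 2 2 1 0 0 0 0 0 2 1 2
CB0001 2 1 0 0 2 2 1 2 0 2 0 1 2 0 0 0 1 0 2 0 1 0 1 2 2 1 1 2 2 1 2 1 0 0 0 2 0 2 1 2
CB0002 2 1 0 0 1 1 1 1 0 1 0 0 2 0 1 0 0 0 2 0 1 0 1 2 2 1 1 2 2 1 2 1 0 0 0 1 0 1 1 1
CB0003 2 1 0 0 0 2 0 2 0 1 1 0 2 1 1 0 0 0 2 0 1 0 2 2 2 1 2 2 2 1 2 1 0 0 1 1 1 2 2 1
CB0004 2 1 0 0 2 1 0 2 0 1 0 0 2 0 1 1 1 0 2 0 1 0 2 2 2 1 2 2 2 1 2 1 0 0 1 1 0 1 2 2
CB0009 2 1 0 0 0 2 0 0 0 1 1 0 1 0 0 1 1 0 2 1 1 0 2 2 2 0 2 1 2 2 2 1 0 1 1 2 2 1 1 1
CB0010 2 2 0 1 1 2 0 1 0 2 1 0 1 1 0 0 0 0 2 1 1 0 2 2 2 1 0 2 2 2 2 1 1 0 0 2 2 2 1 2
CB0011 2 1 0 0 0 1 0 1 0 2 2 0 2 1 0 0 0 0 2 0 1 0 2 2 2 1 1 1 2 1 1 1 1 0 0 2 2 2 1 2
CB0012 2 1 0 1 1 2 0 1 0 2 2 0 1 1 0 0 1 0 2 1 1 0 2 2 2 0 2 1 2 1 1 1 0 1 1 1 1 1 1 2
CB0017 2 2 0 0 1 1 0 2 0 2 0 0 2 1 0 0 1 0 2 0 0 1 1 2 2 0 1 2 2 1 2 1 2 0 1 1 1 2 0 2
CB0018 2 2 0 1 1 0 1 2 0 1 0 0 2 0 1 0 1 0 2 1 0 1 2 2 2 0 2 2 2 2 2 1 2 0 2 2 2 2 2 2
CB0019 2 2 0 0 1 2 0 2 0 2 0 0 2 0 1 0 2 0 2 1 0 1 2 2 2 0 0 2 2 2 2 2 2 0 1 2 1 2 1 2
CB0020 2 2 0 0 0 1 0 2 0 2 0 0 2 1 0 0 0 0 2 1 1 1 2 2 2 0 1 2 2 1 1 1 2 0 1 1 1 2 1 2
CB0013 2 2 0 0 2 1 1 2 0 1 0 0 2 0 1 0 2 0 2 1 0 0 2 2 1 0 1 1 2 2 2 1 1 0 2 0 2 2 0 2
CB0014 2 1 0 0 1 0 1 2 0 1 0 0 2 1 1 0 2 0 2 1 0 1 2 2 2 0 1 1 2 2 2 1 1 0 2 0 1 2 1 2
CB0015 2 1 0 0 1 0 0 2 0 1 0 0 2 2 1 0 2 0 1 1 1 1 2 2 1 0 1 1 2 1 2 1 1 0 2 0 2 2 1 2
CB0016 2 1 0 0 1 2 0 2 0 1 0 0 2 1 1 0 2 0 2 1 0 0 2 2 2 0 1 1 2 1 2 1 1 0 2 0 2 2 2 2
CB0005 2 1 0 0 1 2 0 1 1 1 1 0 2 0 1 0 2 1 1 0 1 1 2 2 2 0 2 2 2 1 1 0 1 0 1 2 1 1 1 2
CB0006 2 1 0 0 1 1 1 2 0 1 1 0 2 0 2 1 1 1 2 1 2 1 2 2 2 1 1 2 1 1 2 1 1 0 0 2 2 2 0 2
CB0007 2 1 0 0 1 2 1 0 1 1 1 0 2 0 2 1 2 1 1 1 1 2 2 2 2 1 1 2 2 1 1 1 1 0 1 2 0 2 1 2
CB0008 2 1 0 0 1 1 0 0 1 2 1 0 2 0 1 1 1 0 2 1 2 2 2 2 2 1 1 2 1 0 1 0 1 0 0 2 1 2 0 2
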
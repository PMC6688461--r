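word,language,source
baada,sw,common
bila,sw,common
cha,sw,common
gani,sw,common
hii,sw,common
hilo,sw,common
hivi,sw,common
hiyo,sw,common
huo,sw,common
ili,sw,common
ipi,sw,common
je,sw,common
kabisa,sw,common
kama,sw,common
karibu,sw,common
kati,sw,common
katika,sw,common
kila,sw,common
kuhusu,sw,common
kutoka,sw,common
kwa,sw,common
kwamba,sw,common
kwenye,sw,common
la,sw,common
lakini,sw,common
langu,sw,common
lini,sw,common
mara,sw,common
mimi,sw,common
moja,sw,common
na,sw,common
nafanya,sw,custom
nahitaji,sw,custom
nataka,sw,custom
nawe,sw,common
ngapi,sw,common
ni,sw,common
niambie,sw,custom
nifanye,sw,custom
nini,sw,common
nipate,sw,custom
pia,sw,common
sana,sw,common
sasa,sw,common
si,sw,common
tena,sw,common
tu,sw,common
vipi,sw,common
vizuri,sw,common
wa,sw,common
wakati,sw,common
wake,sw,common
wako,sw,common
wangu,sw,common
wapi,sw,common
wewe,sw,common
ya,sw,common
yake,sw,common
yako,sw,common
yangu,sw,common
yapi,sw,common
yeye,sw,common
za,sw,common
zake,sw,common
zangu,sw,common
zipi,sw,common
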
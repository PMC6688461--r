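nataka kujua kuhusu uzazi wa mpango
niambie kuhusu madhara ya vidonge
je ninaweza kupata mimba baada ya sindano
jinsi ya kuzuia mimba mapema
nahitaji ushauri kuhusu njia za uzazi
njia gani ya kupanga uzazi ni salama
hedhi yangu haiji vizuri nifanye nini
nimekosa hedhi je nina mimba
dawa za dharura zinapatikana wapi
bei ya kipandikizi ni ngapi
madhara ya njia za uzazi ni yapi
asante kwa msaada wako kuhusu afya
siku salama ni zipi baada ya hedhi
nahesabu vipi siku salama za mzunguko
hedhi yangu imechelewa nina wasiwasi
nimekosa hedhi baada ya tendo bila kinga
dawa ya dharura inafanya kazi baada ya siku ngapi
sindano inaweza kuchelewesha hedhi yangu
nataka kupata mtoto nianze lini
njia gani inafaa mama wa watoto wawili
naweza kutoa kipandikizi ili nipate mimba
dalili za saratani ya matiti ni zipi
saratani ya mlango wa kizazi husababishwa na nini
nipime wapi saratani ya kizazi
je tendo bila kinga ni salama mara moja
kondomu inaweza kupasuka wakati wa tendo
natumia vipi kondomu kwa usahihi
kondomu zinazuia ukimwi kabisa
mpenzi wangu amekosa hedhi baada ya tendo
nipate wapi kondomu za bure
njia gani ya uzazi inafaa mke wangu
tunawezaje kupanga nafasi ya watoto
nini husababisha mbegu chache kwa wanaume
dalili za saratani ya tezi dume ni zipi
tezi dume hupimwa vipi mapema
nini husababisha kuvimba kwa tezi dume
habari yako karibu kwenye huduma yetu ya afya
tunakushukuru kwa ujumbe wako tutakujibu hivi karibuni
mwili wa binadamu hubadilika kulingana na umri
ni vizuri kumwona daktari ukiona dalili zozote
kliniki iliyo karibu nawe inatoa huduma bila malipo
matumizi sahihi ya kondomu huzuia maambukizi
kunyonyesha mtoto ni muhimu kwa afya yake
kupima afya mara kwa mara ni jambo la busara
usisite kuuliza swali lolote kuhusu afya yako
elimu ya afya ya uzazi huwasaidia vijana wengi
wasichana na wavulana wanahitaji taarifa sahihi
maumivu makali ya tumbo yanahitaji uchunguzi
dawa hizi zinapatikana katika duka la dawa
mzunguko wa hedhi hutofautiana kati ya wanawake
ushauri wa kitaalamu unapatikana siku zote
wanawake wengi hutumia sindano ya kupanga uzazi
vidonge vya dharura vinafaa ndani ya siku tatu
hedhi ya kwanza huja katika umri wa kubalehe
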
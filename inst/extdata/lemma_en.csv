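inflected,lemma
babies,baby
breasts,breast
cancers,cancer
causes,cause
chances,chance
children,child
clinics,clinic
coils,coil
condoms,condom
conceiving,conceive
counts,count
cramps,cramp
cycles,cycle
days,day
delays,delay
doctors,doctor
drugs,drug
effects,effect
enlargements,enlargement
families,family
hormones,hormone
hospitals,hospital
husbands,husband
implants,implant
infections,infection
injections,injection
methods,method
missed,miss
mothers,mother
myths,myth
nurses,nurse
options,option
pains,pain
partners,partner
periods,period
pills,pill
pregnancies,pregnancy
prices,price
problems,problem
questions,question
replies,reply
results,result
services,service
signs,sign
symptoms,symptom
tests,test
wives,wife
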
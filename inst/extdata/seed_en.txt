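what is the best method of family planning for me
i want to know about family planning methods
tell me about side effects of the pills
what are the side effects of the injection
can i get pregnant after taking the pill
how do i prevent pregnancy
i need information about contraception
which contraception method is most effective
my periods are irregular what should i do
i have missed my period am i pregnant
how much does the implant cost in ksh
where can i get the emergency pill
which are my safe days after my period
how do i count safe days in my cycle
can i get pregnant during my safe days
my period is late and i am worried
does the emergency pill affect my periods
i missed my period after unprotected sex
does the emergency pill work after two days
which pill is safe while breastfeeding
can the injection delay my periods
i want a method that does not affect my periods
i want to conceive when should we try
which family planning method suits a mother of two
can i remove the implant to conceive
how long after the injection can i conceive
is the coil good for spacing children
what are signs of breast cancer
how do i check my breasts for cancer
what causes cervical cancer in women
where can i screen for cervical cancer
is family planning safe at my age
is unprotected sex safe one time
can a condom burst during sex
how do i use a condom correctly
can kissing transmit hiv
does withdrawal prevent pregnancy during sex
can condoms prevent hiv completely
is oral sex safe from infection
my girlfriend missed her period after sex
how soon can an hiv test detect the virus
where can i get free condoms
which family planning method is best for my wife
does vasectomy affect performance
how can we space our children
can stress lower fertility in men
what causes low sperm count
what are symptoms of prostate cancer
how is prostate cancer detected early
is prostate screening painful
at what age should i test my prostate
can prostate problems affect urination
what causes prostate enlargement in men
does prostate cancer run in families
what raises the risk of cancer in men
thank you for your question here is the information you requested
the most common side effects are mild and pass within a few days
you can visit your nearest clinic for free family planning services
the emergency pill works best within three days of unprotected sex
please let us know if you have any other questions about your health
a nurse will follow up with more details about your question
condoms used correctly protect against both pregnancy and infection
your cycle can vary from month to month and that can be normal
thank you for contacting the service we are happy to help
drink plenty of water and rest if you feel unwell
regular checkups help detect problems early
every method has benefits and drawbacks to consider
your information is kept private and confidential
you can ask any question about your health at any time
it is normal to have questions about your changing body
a balanced diet supports a healthy pregnancy
many young people share the same worries about their health
screening services are available at county hospitals
talk to a trusted adult or a nurse about your concerns
the implant and the coil are long acting methods
missing a single pill can reduce protection
pain that lasts more than a few days needs attention
an irregular cycle is common in the first years of menstruation
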
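bigram
birth control
emergency pill
family planning
menstrual cycle
morning after
safe day
safe days
side effect
side effects
sperm count
tubal ligation
unprotected sex
unsafe days
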
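variant,canonical
contraceptive,contraception
contraceptives,contraception
fp,family planning
menses,period
menstruation,period
postinor,p2
preggy,pregnant
prego,pregnant
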
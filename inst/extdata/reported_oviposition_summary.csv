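group,species,censoring,regime,mean,se,n
predator:uncensored:extreme,predator,uncensored,extreme,3.199,0.115,93
predator:uncensored:mild,predator,uncensored,mild,1.788,0.111,86
prey:uncensored:extreme,prey,uncensored,extreme,10.889,0.667,79
prey:uncensored:mild,prey,uncensored,mild,8.696,0.275,101
predator:censored:extreme,predator,censored,extreme,3.11,0.274,15
predator:censored:mild,predator,censored,mild,2.12,0.180,25
prey:censored:extreme,prey,censored,extreme,13.957,0.619,46
prey:censored:mild,prey,censored,mild,9.824,0.183,62
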
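{"model":"combined","smp":{"model":"clogit","C":0.4,"L50":30,"SR":6},"codend":{"model":"logit","L50":24,"SR":4},"config":{"total":500,"m":10,"between_haul_sd":0.05,"seed":2}}
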
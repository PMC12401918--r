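"day","type","magnitude"
2016-01-06,"onset_shift",3
2016-01-10,"fragmentation",4
2016-01-10,"night_appliance",3051
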
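country,grouping,g2020,g_decade_mean,prev_2019,pop_u5
India,South Asia,-7.3,7.6,20.8,116813764
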
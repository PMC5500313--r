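measure,group,value_2015,value_2025
disability_cases_65plus_thousands,all,2251,2811
le65_total,all,20.1,21.8
le65_disability_free,all,15.4,16.4
le65_disabled,all,4.7,5.4
le65_total,men,19.0,21.7
le65_disability_free,men,14.9,16.5
le65_disabled,men,4.1,5.2
le65_total,women,21.0,22.1
le65_disability_free,women,15.8,16.4
le65_disabled,women,5.2,5.7
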
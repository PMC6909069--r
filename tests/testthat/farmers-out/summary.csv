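"class","strategy","initial_count","final_count","initial_wealth","final_wealth","survival"
"poor","titfortat",39,9,156,72.8200000000001,0.230769230769231
"rich","titfortat",40,28,400,315.419999999998,0.7
"poor","subsist",33,30,132,181.379999999999,0.909090909090909
"rich","subsist",36,33,360,346.639999999996,0.916666666666667
"poor","exploit",49,17,196,130.93,0.346938775510204
"rich","exploit",37,26,370,606.519999999999,0.702702702702703
"poor","thief",48,23,192,197.109999999999,0.479166666666667
"rich","thief",39,20,390,248.599999999998,0.512820512820513
"poor","middle",43,39,172,384.389999999997,0.906976744186046
"rich","middle",36,34,360,348.999999999996,0.944444444444444
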
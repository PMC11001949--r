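esa_class,year,share_percent
not affected,1960,14.3
potential,1960,18.0
fragile 1,1960,12.0
fragile 2,1960,10.0
fragile 3,1960,12.0
critical 1,1960,5.0
critical 2,1960,3.7
critical 3,1960,25.0
not affected,2000,70.0
potential,2000,8.8
fragile 1,2000,6.0
fragile 2,2000,5.0
fragile 3,2000,4.0
critical 1,2000,3.0
critical 2,2000,3.2
critical 3,2000,0.0
not affected,2020,35.0
potential,2020,17.7
fragile 1,2020,12.0
fragile 2,2020,10.0
fragile 3,2020,9.0
critical 1,2020,7.0
critical 2,2020,6.0
critical 3,2020,3.3
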
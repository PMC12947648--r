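"age_start","width","m","sex"
40,5,0.00120653821395804,"all"
45,5,0.00191124579663264,"all"
50,5,0.00302755474537581,"all"
55,5,0.00479587071029642,"all"
60,5,0.00759701402757756,"all"
65,5,0.0120342322847238,"all"
70,5,0.0190631142916116,"all"
75,5,0.0301973834223185,"all"
80,5,0.0478348894941983,"all"
85,5,0.0757740040228455,"all"
90,5,0.120031628511457,"all"
95,5,0.19013898010152,"all"
100,NA,0.301194211912202,"all"
40,5,0.00162882658884335,"male"
45,5,0.00258018182545406,"male"
50,5,0.00408719890625735,"male"
55,5,0.00647442545890016,"male"
60,5,0.0102559689372297,"male"
65,5,0.0162462135843771,"male"
70,5,0.0257352042936757,"male"
75,5,0.0407664676201299,"male"
80,5,0.0645771008171677,"male"
85,5,0.102294905430841,"male"
90,5,0.162042698490466,"male"
95,5,0.256687623137053,"male"
100,NA,0.406612186081472,"male"
40,5,0.000941099806887271,"female"
45,5,0.00149077172137346,"female"
50,5,0.00236149270139313,"female"
55,5,0.0037407791540312,"female"
60,5,0.0059256709415105,"female"
65,5,0.00938670118208454,"female"
70,5,0.0148692291474571,"female"
75,5,0.0235539590694084,"female"
80,5,0.0373112138054747,"female"
85,5,0.0591037231378195,"female"
90,5,0.0936246702389362,"female"
95,5,0.148308404479186,"female"
100,NA,0.234931485291517,"female"
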
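skill_id,skill_name,score
1,Rolls forward 10 m,2
2,Rolls backward 5 m,2
3,Turns 90 degrees by moving forward,1
4,Turns 90 degrees by moving backward,2
5,Turns 180 degrees in place,2
6,Maneuvers sideways,1
7,Gets through gate,2
8,Rolls 100 m,2
9,Avoids moving obstacles,2
10,Ascends small ramp,2
11,Descends small ramp,2
12,Ascends long curved ramp,2
13,Descends long curved ramp,2
14,Rolls 2 m across side-slope,0
15,Rolls 2 m on uneven surface,2
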
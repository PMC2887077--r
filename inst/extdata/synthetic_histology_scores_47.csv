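subject_id,inflammation_grade,fibrosis_stage
BA01,0,2
BA02,1,0
BA03,3,3
BA04,2,3
BA05,2,1
BA06,2,2
BA07,0,1
BA08,2,2
BA09,3,1
BA10,0,1
BA11,3,3
BA12,2,0
BA13,0,3
BA14,2,2
BA15,2,1
BA16,1,2
BA17,0,1
BA18,2,2
BA19,1,3
BA20,2,1
BA21,1,1
BA22,1,1
BA23,1,1
BA24,2,2
BA25,2,2
BA26,3,3
BA27,1,0
BA28,3,1
BA29,2,3
BA30,1,1
BA31,3,1
BA32,1,2
BA33,1,3
BA34,1,2
BA35,2,3
BA36,3,3
BA37,2,0
BA38,3,1
BA39,1,1
BA40,3,0
BA41,2,3
BA42,0,2
BA43,2,0
BA44,1,2
BA45,1,1
BA46,3,0
BA47,1,2
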
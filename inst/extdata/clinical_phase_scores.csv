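measure,hand,phase,session,value
BBT,dominant,baseline,mean,60.5
BBT,dominant,post,1,65
BBT,nondominant,baseline,mean,50.8
BBT,nondominant,post,1,51.5
NHPT,dominant,baseline,mean,0.91
NHPT,dominant,post,1,0.92
NHPT,nondominant,baseline,mean,0.57
NHPT,nondominant,post,1,0.62
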
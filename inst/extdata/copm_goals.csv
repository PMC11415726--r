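goal,performance_pre,performance_post,satisfaction_pre,satisfaction_post
running_without_pain,8,10,7,10
basketball_participation,6,8,5,7
pe_class_participation,7,9,8,8
walking_without_device,9,10,9,10
stair_climbing_speed,9,10,8,10
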
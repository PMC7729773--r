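action,predicted_nonfall,predicted_fall
Walking,92,0
Squat,23,0
StandUpSitDown,76,3
BendOver,65,4
Falling,4,147
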
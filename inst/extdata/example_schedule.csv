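"event","time_s","value"
"step_angle_deg",0,30
"hold_s",0,4
"transition_s",0,0.5
"n_revolutions",0,2
"polarizer_present",0,1
"inactivity_s",0,10
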
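element_type,intensity_class
body_ripple,high
mock_attack,high
wing_flick,low
wing_shiver,low
head_bob,low
bow,low
crouch_display,low
hop,low
run_around,low
decoration_toss,low
decoration_hold,low
bill_wipe,low
tail_flick,low
neck_stretch,low
strut,low
freeze_posture,low
peck_ground,low
wing_droop,low
pivot,low
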
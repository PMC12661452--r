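"time","y"
1,0.152021
1.2,0.090408
1.5,0.055028
2,0.020682
3,0.00226
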
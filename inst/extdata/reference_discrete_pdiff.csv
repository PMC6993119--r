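task,output,metric,pdiff_mean,pdiff_sd
walking straight,kfm,peak,44.3,70.8
90° walking turn,kfm,peak,47.1,60.6
moderate running,kfm,peak,24.7,33.0
fast running,kfm,peak,37.2,68.7
90° running turn,kfm,peak,44.9,45.2
45° cutting maneuver,kfm,peak,44.1,60.7
walking straight,kfm,impulse,27.4,83.9
90° walking turn,kfm,impulse,6.7,31.3
moderate running,kfm,impulse,0.65,37.2
fast running,kfm,impulse,6.8,40.7
90° running turn,kfm,impulse,12.1,46.5
45° cutting maneuver,kfm,impulse,10.0,42.6
walking straight,kam,peak,39.1,101.0
90° walking turn,kam,peak,82.4,110.5
moderate running,kam,peak,68.7,94.5
fast running,kam,peak,123.5,124.1
90° running turn,kam,peak,159.8,157.1
45° cutting maneuver,kam,peak,308.2,356.5
walking straight,kam,impulse,62.0,253.1
90° walking turn,kam,impulse,69.3,127.5
moderate running,kam,impulse,42.7,108.9
fast running,kam,impulse,94.2,145.3
90° running turn,kam,impulse,230.0,179.9
45° cutting maneuver,kam,impulse,470.0,702.0
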
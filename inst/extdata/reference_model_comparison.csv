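task,output,delta_r,delta_rmse,delta_rrmse
walking straight,kfm,0.03,0.00,0.50
90° walking turn,kfm,-0.02,0.03,1.56
moderate running,kfm,-0.02,0.18,1.31
fast running,kfm,-0.03,0.15,0.90
90° running turn,kfm,-0.08,0.11,0.85
45° cutting maneuver,kfm,-0.07,0.44,1.94
walking straight,kam,-0.20,0.05,2.64
90° walking turn,kam,-0.08,0.07,0.09
moderate running,kam,-0.10,0.09,-1.58
fast running,kam,-0.04,0.20,1.87
90° running turn,kam,-0.14,0.16,-0.87
45° cutting maneuver,kam,0.26,0.22,-0.57
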
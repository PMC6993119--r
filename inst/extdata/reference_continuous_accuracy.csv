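task,output,r_mean,r_sd,rmse_mean,rmse_sd,rrmse_mean,rrmse_sd
walking straight,kfm,0.72,0.32,0.26,0.09,18.4,5.3
90° walking turn,kfm,0.69,0.31,0.32,0.10,17.2,3.1
moderate running,kfm,0.85,0.43,0.58,0.20,19.7,7.9
fast running,kfm,0.65,0.43,1.13,0.46,25.5,7.0
90° running turn,kfm,0.79,0.28,0.77,0.20,20.8,4.5
45° cutting maneuver,kfm,0.73,0.41,1.05,0.41,23.1,6.5
walking straight,kam,0.71,0.26,0.18,0.06,22.3,8.3
90° walking turn,kam,0.56,0.33,0.29,0.10,23.9,6.4
moderate running,kam,0.40,0.35,0.37,0.14,34.4,13.5
fast running,kam,0.21,0.47,0.80,0.46,33.8,8.5
90° running turn,kam,0.51,0.22,0.62,0.19,27.9,3.9
45° cutting maneuver,kam,-0.05,0.30,0.92,0.54,37.2,7.8
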
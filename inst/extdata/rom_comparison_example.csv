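task,joint,rom_lmc,rom_qtm,qtm_minus_lmc
thumb_abduction,thumb_ip,31.26,37.75,6.49
thumb_abduction,thumb_mcp,41.38,49.65,8.27
thumb_abduction,thumb_cmc,54.10,42.44,-11.66
thumb_flexion,thumb_ip,43.86,72.15,28.29
thumb_flexion,thumb_mcp,43.16,62.47,19.31
thumb_flexion,thumb_cmc,53.66,45.73,-7.93
index_flexion,index_dip,68.78,68.31,-0.47
index_flexion,index_pip,81.09,81.34,0.25
index_flexion,index_mcp,107.86,86.66,-21.2
middle_flexion,middle_dip,33.80,21.38,-12.42
middle_flexion,middle_pip,43.59,105.10,61.51
middle_flexion,middle_mcp,72.36,92.64,20.28
ring_flexion,ring_dip,47.49,19.86,-27.63
ring_flexion,ring_pip,69.55,103.94,34.39
ring_flexion,ring_mcp,78.89,83.39,4.5
pinky_flexion,pinky_dip,41.16,50.32,9.16
pinky_flexion,pinky_pip,57.35,94.68,37.33
pinky_flexion,pinky_mcp,78.08,95.61,17.53
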
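label,t_mz,n_probands_mz,t_dz,n_probands_dz
eq2_mild,0.44,270,0.17,711
ge2_mild_profound,0.43,434,0.14,1126
ge3_severe_profound,0.42,164,0.11,415
ge4_profound,0.45,53,0.11,139
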
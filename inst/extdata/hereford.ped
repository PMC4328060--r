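FAM1 IV/A 0 0 2 1 1
FAM1 IV/B 0 0 1 1 0
FAM1 III/C 0 0 2 1 0
FAM1 II/2 0 0 0 1 0
FAM1 III/A IV/B IV/A 1 1 1
FAM1 III/B IV/B IV/A 2 1 0
FAM1 II/C III/A III/C 1 1 1
FAM1 case1 III/A IV/A 2 2 1
FAM1 case2 III/A III/B 0 2 1
FAM1 case3 II/C III/B 1 2 1
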
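family,model,DIC,PPP
Z,S + n,2676.3,0.0001
Z,S + n + L,2678.5,0.0001
Z,S + n + L + L2,2680.9,0.0001
Z,S + n + R,2676.2,0.0001
Z,S + n + L + R,2677.1,0.0001
Z,S + n + L + L2 + R,2680.2,0.0001
H,S + M + n,-661.8,0.0001
H,S + M + n + L,-681.2,0.986
H,S + M + n + L + L2,-692.1,0.032
H,S + M + n + R,-697.2,0.0001
H,S + M + n + L + R,-711.8,0.914
H,S + M + n + L + L2 + R,-715.5,0.362
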
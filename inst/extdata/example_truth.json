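{"note":"synthetic alignment simulated under model RY5.6b on example_tree.nwk","model":"RY5.6b","b":[0.5,0.2,0.3,-0.2],"trace":-4,"heterogeneity":"single","n_sites":300,"seed":2026}
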
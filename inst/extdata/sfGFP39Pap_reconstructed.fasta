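>sfGFP39Pap_reconstructed synthetic reconstruction; X = p-(phenylazo)-L-phenylalanine at 39; C-terminal SA-linked Strep-tag II
MSKGEELFTGVVPILVELDGDVNGHKFSVRGEGEGDATXGKLTLKFICTTGKLPVPWPTL
VTTLTYGVQCFSRYPDHMKRHDFFKSAMPEGYVQERTISFKDDGTYKTRAEVKFEGDTLV
NRIELKGIDFKEDGNILGHKLEYNFNSHNVYITADKQKNGIKANFKIRHNVEDGSVQLAD
HYQQNTPIGDGPVLLPDNHYLSTQSVLSKDPNEKRDHMVLLEFVTAAGITHGMDELYKSA
WSHPQFEK
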
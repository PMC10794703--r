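# Chain mapping template: chain id -> layer,fragment
# Stacked-chain convention: consecutive chains are consecutive layers, two
# chains (N- and C-terminal fragment) per layer. UNVERIFIED against the
# deposition -- inspect the entry and edit before use; read_structure()
# accepts any mapping file of this format.
A = 0,N
B = 0,C
C = 1,N
D = 1,C
E = 2,N
F = 2,C
G = 3,N
H = 3,C
I = 4,N
J = 4,C
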
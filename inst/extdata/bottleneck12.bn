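# two dense five/six-node clusters joined only through the sparse bridge B:
# every left-to-right shortest path crosses B, and B fully determines its
# two targets, so B scores top on betweenness and determinative power while
# staying low-degree -- the engineered gatekeeper
targets, factors
L1, L2 & L3 & L4
L2, L3 & L4 & L5
L3, L4 & L5 & L1
L4, L5 & L1 & L2
L5, L1 & L2 & L3
B, L3 | L5
R1, B
R2, B
R3, R1 & R2 & R6
R4, R1 | R2 | R3
R5, R2 & R3 & R4
R6, R3 | R4 | R5
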
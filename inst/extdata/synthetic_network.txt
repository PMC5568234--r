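# synthetic_network.txt -- randomly generated Erdos-Renyi G(30, 0.12)
# toy stand-in for a protein interaction network; NOT real data
prot01 prot19
prot01 prot26
prot02 prot08
prot02 prot10
prot02 prot16
prot02 prot28
prot03 prot17
prot03 prot23
prot03 prot26
prot04 prot08
prot04 prot09
prot04 prot12
prot04 prot30
prot05 prot12
prot06 prot09
prot06 prot13
prot06 prot29
prot07 prot17
prot08 prot21
prot08 prot22
prot08 prot24
prot09 prot19
prot10 prot14
prot10 prot19
prot10 prot22
prot10 prot26
prot10 prot28
prot11 prot21
prot11 prot23
prot12 prot30
prot13 prot19
prot13 prot21
prot13 prot27
prot14 prot15
prot14 prot18
prot14 prot26
prot14 prot29
prot16 prot18
prot16 prot28
prot17 prot18
prot17 prot19
prot17 prot26
prot19 prot21
prot19 prot24
prot19 prot28
prot19 prot29
prot20 prot27
prot20 prot30
prot22 prot23
prot22 prot24
prot22 prot29
prot23 prot25
prot24 prot30
prot25 prot26
prot26 prot27
prot28 prot30
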
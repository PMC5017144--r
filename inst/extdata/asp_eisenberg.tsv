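# Atomic solvation parameters, five-class Eisenberg-McLachlan set
# units: cal/(mol*Angstrom^2)
class	asp
C	16
N/O	-6
O-	-24
N+	-50
S	21
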
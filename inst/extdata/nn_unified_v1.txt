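# hybriclass nearest-neighbor parameter table, version 1
#
# Watson-Crick nearest-neighbor dinucleotide stack enthalpies (dH, kcal/mol)
# and entropies (dS, cal/(mol*K)) from the unified oligonucleotide set of
# SantaLucia (1998), PNAS 95:1460-1465, Table 1 (1 M NaCl). Stacks are keyed
# by the top-strand dinucleotide read 5'->3'; the six dinucleotides not
# listed are the reverse complements of listed keys and share their values.
# A single duplex-initiation term is used (the unified set's symmetric
# initiation); terminal-AT corrections, dangling ends and salt corrections
# are outside this model's scope.
#
# mismatch_penalty_dG, loop_open_dG and loop_extend_dG (kcal/mol) are this
# package's own fixed penalties for internal mismatches and interior
# unpaired stretches; they are deliberately simple single constants rather
# than full mismatch/loop tables (see the package vignette).
#
# format: whitespace-separated records
#   stack <dinucleotide> <dH> <dS>
#   init <dH> <dS>
#   const <name> <value>

stack AA -7.9 -22.2
stack AT -7.2 -20.4
stack TA -7.2 -21.3
stack CA -8.5 -22.7
stack GT -8.4 -22.4
stack CT -7.8 -21.0
stack GA -8.2 -22.2
stack CG -10.6 -27.2
stack GC -9.8 -24.4
stack GG -8.0 -19.9
init 0.2 -5.7
const mismatch_penalty_dG 1.0
const loop_open_dG 3.0
const loop_extend_dG 0.5
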
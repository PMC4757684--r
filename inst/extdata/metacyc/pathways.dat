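# Synthetic MetaCyc-style pathway records (hand-written test fixture; not
# MetaCyc content).
UNIQUE-ID - PWY-CHAIN
COMMON-NAME - toy linear degradation
REACTION-LIST - RXN-1
REACTION-LIST - RXN-2
REACTION-LIST - RXN-3
PREDECESSORS - (RXN-2 RXN-1)
PREDECESSORS - (RXN-3 RXN-2)
//
UNIQUE-ID - PWY-DIAMOND
COMMON-NAME - toy branched degradation
REACTION-LIST - RXN-1
REACTION-LIST - RXN-2
REACTION-LIST - RXN-4
REACTION-LIST - RXN-3
PREDECESSORS - (RXN-2 RXN-1)
PREDECESSORS - (RXN-4 RXN-1)
PREDECESSORS - (RXN-3 RXN-2)
PREDECESSORS - (RXN-3 RXN-4)
//
UNIQUE-ID - PWY-MISSING
COMMON-NAME - refers to an undefined reaction
REACTION-LIST - RXN-1
REACTION-LIST - RXN-NOPE
//
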
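# Synthetic MetaCyc-style reaction records (hand-written test fixture).
UNIQUE-ID - RXN-1
COMMON-NAME - first step
SPECIES - ORG-PPUT
SPECIES - ORG-FLAV
//
UNIQUE-ID - RXN-2
COMMON-NAME - second step
SPECIES - ORG-FLAV
//
UNIQUE-ID - RXN-3
COMMON-NAME - third step
SPECIES - ORG-NITR
//
UNIQUE-ID - RXN-4
COMMON-NAME - alternative second step
SPECIES - ORG-PPUT
//
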
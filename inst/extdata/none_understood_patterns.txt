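# negation patterns for the "understood by no one" detector
no one
nobody
not really
none
no people
not anyone
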
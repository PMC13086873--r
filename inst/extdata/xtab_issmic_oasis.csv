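call_a,call_b,n
positive,positive,65
positive,negative,25
negative,positive,5
negative,negative,25
equivocal,positive,0
equivocal,negative,15
inconclusive,positive,12
inconclusive,negative,60
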
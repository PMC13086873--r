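call_a,call_b,n
positive,positive,126
positive,negative,17
negative,positive,8
negative,negative,89
equivocal,positive,26
equivocal,negative,19
inconclusive,positive,1
inconclusive,negative,0
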
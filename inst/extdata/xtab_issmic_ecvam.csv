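call_a,call_b,n
positive,positive,73
positive,negative,11
positive,equivocal,16
positive,inconclusive,1
negative,positive,2
negative,negative,32
negative,equivocal,4
negative,inconclusive,0
equivocal,positive,11
equivocal,negative,3
equivocal,equivocal,8
equivocal,inconclusive,0
inconclusive,positive,8
inconclusive,negative,45
inconclusive,equivocal,11
inconclusive,inconclusive,1
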
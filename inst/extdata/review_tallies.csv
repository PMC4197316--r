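intent,reviewed,tp,fp,fn
CHEMO,54125,53932,193,NA
PROCEDURE,45855,45249,606,NA
INFECTION,28887,28255,632,750
TOXICITY,39485,38565,920,1001
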
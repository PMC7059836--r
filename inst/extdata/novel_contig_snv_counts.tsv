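region	this_work	lift_over
novel	1019976	811817
existing	70809835	76588820
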
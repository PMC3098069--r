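id	kind	name_giving
TOY:0000001	object
TOY:0000002	object
TOY:0000003	object
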
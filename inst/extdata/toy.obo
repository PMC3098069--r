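format-version: 1.2
ontology: toy

[Term]
id: TOY:0000001
name: molecule
relationship: part_of TOY:0000002 ! cell

[Term]
id: TOY:0000002
name: cell
relationship: part_of TOY:0000003 ! organ
is_a: TOY:0000099 ! anatomical structure

[Term]
id: TOY:0000003
name: organ
is_a: TOY:0000099 ! anatomical structure
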
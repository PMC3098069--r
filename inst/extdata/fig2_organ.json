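{
  "format_version": "1.0",
  "types": [
    {
      "id": "cell",
      "label": "cell",
      "kind": "object"
    },
    {
      "id": "molecule",
      "label": "molecule",
      "kind": "object"
    },
    {
      "id": "organ",
      "label": "organ",
      "kind": "object"
    },
    {
      "id": "organelle",
      "label": "organelle",
      "kind": "object"
    }
  ],
  "instances": [
    {
      "id": "a",
      "type": "molecule"
    },
    {
      "id": "b",
      "type": "molecule"
    },
    {
      "id": "c",
      "type": "molecule"
    },
    {
      "id": "d",
      "type": "molecule"
    },
    {
      "id": "e",
      "type": "molecule"
    },
    {
      "id": "f",
      "type": "molecule"
    },
    {
      "id": "g",
      "type": "molecule"
    },
    {
      "id": "h",
      "type": "molecule"
    },
    {
      "id": "i",
      "type": "molecule"
    },
    {
      "id": "j",
      "type": "molecule"
    },
    {
      "id": "k",
      "type": "molecule"
    },
    {
      "id": "l",
      "type": "molecule"
    },
    {
      "id": "m",
      "type": "organelle"
    },
    {
      "id": "n",
      "type": "organelle"
    },
    {
      "id": "o",
      "type": "organelle"
    },
    {
      "id": "organ1",
      "type": "organ"
    },
    {
      "id": "p",
      "type": "organelle"
    },
    {
      "id": "q",
      "type": "cell"
    },
    {
      "id": "r",
      "type": "cell"
    }
  ],
  "edges": [
    {
      "child": "a",
      "relation": "direct_proper_part_of",
      "parent": "organ1"
    },
    {
      "child": "b",
      "relation": "direct_proper_part_of",
      "parent": "organ1"
    },
    {
      "child": "c",
      "relation": "direct_proper_part_of",
      "parent": "organ1"
    },
    {
      "child": "d",
      "relation": "direct_proper_part_of",
      "parent": "organ1"
    },
    {
      "child": "e",
      "relation": "direct_proper_part_of",
      "parent": "q"
    },
    {
      "child": "f",
      "relation": "direct_proper_part_of",
      "parent": "q"
    },
    {
      "child": "g",
      "relation": "direct_proper_part_of",
      "parent": "r"
    },
    {
      "child": "h",
      "relation": "direct_proper_part_of",
      "parent": "r"
    },
    {
      "child": "i",
      "relation": "direct_proper_part_of",
      "parent": "m"
    },
    {
      "child": "j",
      "relation": "direct_proper_part_of",
      "parent": "n"
    },
    {
      "child": "k",
      "relation": "direct_proper_part_of",
      "parent": "o"
    },
    {
      "child": "l",
      "relation": "direct_proper_part_of",
      "parent": "p"
    },
    {
      "child": "m",
      "relation": "direct_proper_part_of",
      "parent": "q"
    },
    {
      "child": "n",
      "relation": "direct_proper_part_of",
      "parent": "q"
    },
    {
      "child": "o",
      "relation": "direct_proper_part_of",
      "parent": "r"
    },
    {
      "child": "p",
      "relation": "direct_proper_part_of",
      "parent": "r"
    },
    {
      "child": "q",
      "relation": "direct_proper_part_of",
      "parent": "organ1"
    },
    {
      "child": "r",
      "relation": "direct_proper_part_of",
      "parent": "organ1"
    }
  ]
}
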
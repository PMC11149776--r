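{"family_id":"F2","root":{"children":[{"children":[{"children":[{"event":"leaf","id":"a1","label":"a1","species":"A","taxon":"A"},{"event":"leaf","id":"b1","label":"b1","species":"B","taxon":"B"}],"event":"speciation","id":"XAB","taxon":"AB"},{"event":"leaf","id":"c1","label":"c1","species":"C","taxon":"C"}],"event":"speciation","id":"X","taxon":"R"},{"event":"leaf","id":"a2","label":"a2","species":"A","taxon":"A"}],"event":"duplication","id":"F2root","taxon":"R"}}
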
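name: Synthetica (synthetic 7-country region)
countries:
- synthetica-a.yaml
- synthetica-b.yaml
- synthetica-c.yaml
- synthetica-d.yaml
- synthetica-e.yaml
- synthetica-f.yaml
- synthetica-g.yaml
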
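# Schematic domain ranges (1-based, inclusive) in transcript residue
# coordinates for the RyR2 protomer. The published legend names six regions
# but prints five ranges; labels here are positional and freely editable.
domains:
  - {name: NTD,   start: 1,    end: 639}
  - {name: BSolB, start: 2109, end: 3554}
  - {name: BSolC, start: 3634, end: 4130}
  - {name: CSol,  start: 4490, end: 4886}
  - {name: TMD,   start: 4887, end: 4914}
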
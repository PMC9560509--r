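# OmpA allele classification scheme (synthetic transcription).
#
# The reference is the mature 325-residue K-12-style OmpA chain (21-residue
# signal peptide removed).  Segment boundaries are approximate and
# package-defined; classification-site residue runs for the non-reference
# patterns are synthetic stand-ins chosen to satisfy every published
# constraint of the naming convention (SVE vs DNI at loop 2; the D variation
# in loop 1 carried by VI and VII only; the 7-residue loop 3 of VI and VII;
# alpha matching the K-12 reference at 175/203/251; delta differing from
# alpha at exactly 203 and 251; gamma tied to position-175 variation).
# Corrections to residue identities belong here, never in code.
provenance: >
  Synthetic scheme modeled on the published OmpA allele naming convention;
  reference backbone is the K-12-style mature OmpA sequence.
reference:
  name: K-12-style mature OmpA (synthetic transcription)
  signal_peptide: MKKTAIAIAVALAGFATVAQA
  mature: >-
    APKDNTWYTGAKLGWSQYHDTGFINNNGPTHENQLGAGAFGGYQVNPYVGFEMGYDWLGRMPYKGSVENGAY
    KAQGVQLTAKLGYPITDDLDIYTRLGGMVWRADTKSNVYGKNHDTGVSPVFAGGVEYAITPEIATRLEYQWT
    NNIGDAHTIGTRPDNGMLSLGVSYRFGQGEAAPVVAPAPAPAPEVQTKHFTLKSDVLFNFNKATLKPEGQAA
    LDQLYSQLSNLDPKDGSVVVLGYTDRIGSDAYNQGLSERRAQSVVDYLISKGIPADKISARGMGESNPVTGN
    TCDNVKQRAALIDCLAPDRRVEIEVKGIKDVVTQPQA
segments:
  # N-terminal eight-strand barrel: four surface loops, eight strands.
  - {name: tm1,   start: 6,   end: 18,  surface_exposed: no}
  - {name: loop1, start: 19,  end: 32,  surface_exposed: yes}
  - {name: tm2,   start: 33,  end: 45,  surface_exposed: no}
  - {name: tm3,   start: 50,  end: 57,  surface_exposed: no}
  - {name: loop2, start: 58,  end: 72,  surface_exposed: yes}
  - {name: tm4,   start: 73,  end: 85,  surface_exposed: no}
  - {name: tm5,   start: 91,  end: 96,  surface_exposed: no}
  - {name: loop3, start: 97,  end: 113, surface_exposed: yes}
  - {name: tm6,   start: 114, end: 130, surface_exposed: no}
  - {name: tm7,   start: 131, end: 135, surface_exposed: no}
  - {name: loop4, start: 136, end: 150, surface_exposed: yes}
  - {name: tm8,   start: 151, end: 163, surface_exposed: no}
  # C-terminal domain in the 16-strand 'large pore' model: loops 5-8 exposed,
  # eight further strands; positions 175/203/251 fall between loops.
  - {name: tm9,   start: 196, end: 209, surface_exposed: no}
  - {name: loop5, start: 210, end: 220, surface_exposed: yes}
  - {name: tm10,  start: 221, end: 234, surface_exposed: no}
  - {name: loop6, start: 235, end: 245, surface_exposed: yes}
  - {name: tm11,  start: 246, end: 255, surface_exposed: no}
  - {name: tm12,  start: 256, end: 264, surface_exposed: no}
  - {name: loop7, start: 265, end: 275, surface_exposed: yes}
  - {name: tm13,  start: 276, end: 285, surface_exposed: no}
  - {name: tm14,  start: 286, end: 294, surface_exposed: no}
  - {name: loop8, start: 295, end: 305, surface_exposed: yes}
  - {name: tm15,  start: 306, end: 315, surface_exposed: no}
  - {name: tm16,  start: 316, end: 325, surface_exposed: no}
sites:
  # Variant residue runs inside the four surface loops (N-terminal domain).
  - {name: loop1, kind: loop, start: 25,  end: 27,  classifying: yes}
  - {name: loop2, kind: loop, start: 66,  end: 68,  classifying: yes}
  - {name: loop3, kind: loop, start: 102, end: 110, classifying: yes, variable_length: yes}
  - {name: loop4, kind: loop, start: 144, end: 146, classifying: yes}
  # Single-residue C-terminal domain sites.
  - {name: p175, kind: point, start: 175, end: 175, classifying: yes}
  - {name: p203, kind: point, start: 203, end: 203, classifying: yes}
  - {name: p251, kind: point, start: 251, end: 251, classifying: yes}
  # Transmembrane positions recorded but not used for binning.
  - {name: p93,  kind: point, start: 93,  end: 93,  classifying: no}
  - {name: p129, kind: point, start: 129, end: 129, classifying: no}
  - {name: p161, kind: point, start: 161, end: 161, classifying: no}
nterm_patterns:
  I:   {loop1: "NNN", loop2: "SVE", loop3: "WRADTKSNV", loop4: "TNN"}
  II:  {loop1: "SNN", loop2: "DNI", loop3: "WRGDTKSNV", loop4: "ANN"}
  III: {loop1: "TNN", loop2: "DNI", loop3: "WRADTKSDV", loop4: "TSN"}
  IV:  {loop1: "NNQ", loop2: "SVE", loop3: "WKADTKSNV", loop4: "TNS"}
  V:   {loop1: "NEN", loop2: "SVE", loop3: "WRADEKSNV", loop4: "TGN"}
  VI:  {loop1: "DNN", loop2: "DNI", loop3: "WRADTKV",   loop4: "SNN"}
  VII: {loop1: "DNQ", loop2: "SVE", loop3: "WRADTKS",   loop4: "TNG"}
cterm_patterns:
  alpha: {p175: "A", p203: "N", p251: "G"}
  beta:  {p175: "A", p203: "T", p251: "S"}
  gamma: {p175: "T", p203: "T", p251: "G"}
  delta: {p175: "A", p203: "T", p251: "A"}
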
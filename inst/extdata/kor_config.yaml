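# Receptor analysis configuration: Ballesteros-Weinstein residue map,
# superposition selection (TM helix residue ranges, CA atoms) and
# state-classification thresholds.
residue_map:
  - {code: "2.39", chain: "A", resno: 94,  resname: "THR"}
  - {code: "2.60", chain: "A", resno: 115, resname: "GLN"}
  - {code: "5.39", chain: "A", resno: 227, resname: "LYS"}
  - {code: "6.48", chain: "A", resno: 287, resname: "TRP"}
  - {code: "6.58", chain: "A", resno: 297, resname: "GLU"}
  - {code: "7.43", chain: "A", resno: 320, resname: "TYR"}
  - {code: "7.47", chain: "A", resno: 324, resname: "SER"}
  - {code: "7.48", chain: "A", resno: 325, resname: "LEU"}
  - {code: "8.47", chain: "A", resno: 334, resname: "ASP"}
alignment:
  chain: "A"
  tm_ranges:          # residue ranges whose CA atoms define superposition
    tm2: [85, 91]
    tm3: [140, 146]
    tm5: [230, 236]
thresholds:
  occluded_distance_cutoff: 3.5   # Angstrom, strict <
  tm7_rotation_cutoff: -20        # degrees, strict <
  salt_bridge_cutoff: 4.0         # Angstrom
  w287_down_cutoff: -0.5          # Angstrom, <= counts as downward
  q115_window: 60                 # degrees from reference rotamer
  tm7_sign: 1                     # +1 CCW-positive viewed from extracellular
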
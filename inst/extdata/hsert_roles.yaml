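# Default residue role map for the human serotonin transporter (hSERT),
# author numbering (UniProt P31645).  Transmembrane helix boundaries are
# APPROXIMATE: they derive from topology annotation of the SLC6/NSS fold,
# not from any single deposited structure, and are meant to be edited for a
# given construct.  Gate, anchor and vestibule-limit residues are the
# standard hSERT gating residues.
roles:
  TM1a: {chain: A, resid: "87-98"}
  TM1b: {chain: A, resid: "99-117"}
  TM2:  {chain: A, resid: "123-150"}
  TM3:  {chain: A, resid: "159-192"}
  TM4:  {chain: A, resid: "236-260"}
  TM5:  {chain: A, resid: "264-290"}
  TM6a: {chain: A, resid: "324-337"}
  TM6b: {chain: A, resid: "342-353"}
  TM7:  {chain: A, resid: "360-387"}
  TM8:  {chain: A, resid: "419-446"}
  TM9:  {chain: A, resid: "453-478"}
  TM10: {chain: A, resid: "484-510"}
  TM11: {chain: A, resid: "517-542"}
  TM12: {chain: A, resid: "553-580"}
  hash: {union: [TM3, TM4, TM8, TM9]}
  EC_gate_salt: {chain: A, resid: [104, 493]}        # R104 (TM1b) - E493 (TM10)
  EC_gate_lid:  {chain: A, resid: [176, 335]}        # Y176 (TM3) - F335 (TM6a)
  IC_gate_pairs:                                     # cytoplasmic network
    chain: A
    pairs: [[79, 452], [82, 350], [350, 444], [444, 462]]
  amine_partners: {chain: A, resid: [95, 98, 335, 336]}   # Y95 D98 F335 S336
  site_anchors_ec: {chain: A, resid: [176, 335]}
  site_anchor_cyt: {chain: A, resid: [341]}          # F341, unwound TM6
  ec_vestibule_limit: {chain: A, resid: [104, 493]}
  ic_vestibule_limit: {chain: A, resid: [89, 277]}   # L89 (TM1a), S277 (TM5)
  EL2_range: {chain: A, resid: "193-235"}
  termini_ranges: {chain: A, resid: ["1-86", "581-630"]}
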
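[
  {"name": "E<25/24h", "e_entry_mev": 25, "t_irr_h": 24, "current_ua": 1},
  {"name": "E<30/24h", "e_entry_mev": 30, "t_irr_h": 24, "current_ua": 1},
  {"name": "E<35/24h", "e_entry_mev": 35, "t_irr_h": 24, "current_ua": 1},
  {"name": "E<40/24h", "e_entry_mev": 40, "t_irr_h": 24, "current_ua": 1},
  {"name": "E<25/80h", "e_entry_mev": 25, "t_irr_h": 80, "current_ua": 1},
  {"name": "E<30/80h", "e_entry_mev": 30, "t_irr_h": 80, "current_ua": 1},
  {"name": "E<35/80h", "e_entry_mev": 35, "t_irr_h": 80, "current_ua": 1},
  {"name": "E<40/80h", "e_entry_mev": 40, "t_irr_h": 80, "current_ua": 1}
]
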
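{
  "Faecalibacterium prausnitzii": {"taxid": "853", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Roseburia hominis": {"taxid": "301301", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Roseburia intestinalis": {"taxid": "166486", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Ruminococcus bromii": {"taxid": "40518", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Ruminococcus torques": {"taxid": "33039", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Eubacterium rectale": {"taxid": "39491", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Anaerostipes hadrus": {"taxid": "649756", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Coprococcus eutactus": {"taxid": "33043", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Butyrivibrio fibrisolvens": {"taxid": "831", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Prevotella copri": {"taxid": "165179", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Bacteroides fragilis": {"taxid": "817", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Bacteroides uniformis": {"taxid": "820", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Akkermansia muciniphila": {"taxid": "239935", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Bifidobacterium longum": {"taxid": "216816", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Bifidobacterium adolescentis": {"taxid": "1680", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Blautia obeum": {"taxid": "40520", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Dialister invisus": {"taxid": "218538", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Alistipes putredinis": {"taxid": "28117", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Escherichia coli": {"taxid": "562", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Klebsiella pneumoniae": {"taxid": "573", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Enterococcus faecalis": {"taxid": "1351", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Ruminococcus gnavus": {"taxid": "33038", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Streptococcus salivarius": {"taxid": "1304", "retrieved_at": "2025-06-01T00:00:00Z"},
  "Veillonella parvula": {"taxid": "29466", "retrieved_at": "2025-06-01T00:00:00Z"}
}
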
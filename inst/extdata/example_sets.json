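[
  {
    "set_id": "butyrate_producers",
    "display_name": "Butyrate producing gut bacteria",
    "category": "metabolite_producers",
    "members": ["853", "301301", "166486", "39491", "649756", "33043", "831"],
    "source": "curated example"
  },
  {
    "set_id": "propionate_producers",
    "display_name": "Propionate producing gut bacteria",
    "category": "metabolite_producers",
    "members": ["165179", "817", "820", "239935", "218538", "29466"],
    "source": "curated example"
  },
  {
    "set_id": "acetate_producers",
    "display_name": "Acetate producing gut bacteria",
    "category": "metabolite_producers",
    "members": ["216816", "1680", "40520", "28117", "33038"],
    "source": "curated example"
  },
  {
    "set_id": "proteobacteria_bloom",
    "display_name": "Taxa expanding in dysbiosis",
    "category": "health_disease",
    "members": ["562", "573", "1351", "1304", "29466"],
    "source": "curated example"
  }
]
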
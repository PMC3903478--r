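[
  {
    "id": "SYN_PAL_ANCHOR",
    "family": "PAL",
    "mio_start": 152,
    "dyad_start": 83,
    "note": "synthetic anchor: generated scaffold with planted ASG tripeptide and selectivity dyad; substitute curated reference sequences for real analyses"
  },
  {
    "id": "SYN_HAL_ANCHOR",
    "family": "HAL",
    "mio_start": 152,
    "dyad_start": 83,
    "note": "synthetic anchor: generated scaffold with planted ASG tripeptide and selectivity dyad; substitute curated reference sequences for real analyses"
  },
  {
    "id": "SYN_TAL_ANCHOR",
    "family": "TAL",
    "mio_start": 152,
    "dyad_start": 83,
    "note": "synthetic anchor: generated scaffold with planted ASG tripeptide and selectivity dyad; substitute curated reference sequences for real analyses"
  }
]
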
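[
  {
    "id": "ptm_1",
    "cell_types": ["CL_0000057", "CL_0000091", "CL_0000115", "CL_0000182", "CL_0000632"],
    "location": "liver"
  },
  {
    "id": "ptm_2",
    "cell_types": ["CL_0000057", "CL_0000115", "CL_0000746", "CL_0002068"],
    "location": "heart"
  },
  {
    "id": "ptm_3",
    "cell_types": ["CL_0000057", "CL_0000082", "CL_0000115", "CL_0000158", "CL_0002598"],
    "location": "lung"
  },
  {
    "id": "ptm_4",
    "cell_types": ["CL_0000057", "CL_0000115", "CL_0002071", "CL_1000320"],
    "location": "colon"
  },
  {
    "id": "ptm_5",
    "cell_types": ["CL_0000057", "CL_0000115", "CL_0000508", "CL_0002182", "CL_1000323"],
    "location": "stomach"
  }
]
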
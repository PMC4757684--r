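{
  "reactions": {
    "RXN-ALT": {
      "name": "alternative hydrolysis",
      "organisms": [
        [
          [
            "domain",
            "Bacteria"
          ],
          [
            "genus",
            "Pseudomonas"
          ]
        ]
      ]
    },
    "RXN-HYD": {
      "name": "hydrolysis",
      "organisms": [
        [
          [
            "domain",
            "Bacteria"
          ],
          [
            "genus",
            "Flavobacterium"
          ]
        ]
      ]
    },
    "RXN-OX": {
      "name": "primary oxidation",
      "organisms": [
        [
          [
            "domain",
            "Bacteria"
          ],
          [
            "genus",
            "Pseudomonas"
          ],
          [
            "species",
            "Pseudomonas fluorescens"
          ]
        ],
        [
          [
            "domain",
            "Bacteria"
          ],
          [
            "genus",
            "Pseudomonas"
          ],
          [
            "species",
            "Pseudomonas putida"
          ]
        ]
      ]
    },
    "RXN-RED": {
      "name": "reduction",
      "organisms": [
        [
          [
            "domain",
            "Bacteria"
          ],
          [
            "genus",
            "Nitrospira"
          ]
        ]
      ]
    }
  },
  "pathways": {
    "PWY-BRANCHED": {
      "name": "toy branched degradation",
      "keywords": [
        "degradation"
      ],
      "stages": [
        {
          "reaction": "RXN-OX"
        },
        {
          "parallel": [
            [
              {
                "reaction": "RXN-HYD"
              }
            ],
            [
              {
                "reaction": "RXN-ALT"
              }
            ]
          ]
        },
        {
          "reaction": "RXN-RED"
        }
      ]
    },
    "PWY-SERIAL": {
      "name": "toy degradation pathway",
      "keywords": [
        "degradation"
      ],
      "stages": [
        {
          "reaction": "RXN-OX"
        },
        {
          "reaction": "RXN-HYD"
        }
      ]
    }
  },
  "source_note": "bundled synthetic example database"
}
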
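{
  "format": "metnets-model",
  "version": 1,
  "compartments": [
    {
      "identifier": "c1",
      "name": "compartment 1"
    },
    {
      "identifier": "c2",
      "name": "compartment 2"
    }
  ],
  "processes": [
    {
      "identifier": "P1",
      "name": "pathway 1"
    }
  ],
  "metabolites": [
    {
      "identifier": "A",
      "name": "metabolite A",
      "formula": "",
      "charge": 0,
      "references": {
        "pubchem": [
          "90001"
        ]
      }
    },
    {
      "identifier": "B",
      "name": "metabolite B",
      "formula": "",
      "charge": 0,
      "references": {
        "pubchem": [
          "90002"
        ]
      }
    },
    {
      "identifier": "C",
      "name": "metabolite C",
      "formula": "",
      "charge": 0,
      "references": {
        "pubchem": [
          "90003"
        ]
      }
    },
    {
      "identifier": "D",
      "name": "metabolite D",
      "formula": "",
      "charge": 0,
      "references": {
        "pubchem": [
          "90004"
        ]
      }
    }
  ],
  "reactions": [
    {
      "identifier": "R1_c1",
      "name": "R1_c1",
      "reversible": false,
      "participants": [
        {
          "metabolite": "A",
          "role": "reactant",
          "compartment": "c1",
          "stoichiometry": 1
        },
        {
          "metabolite": "B",
          "role": "product",
          "compartment": "c1",
          "stoichiometry": 1
        }
      ],
      "processes": [
        "P1"
      ],
      "genes": [
        "gene_R1_c1"
      ],
      "references": {},
      "behavior": "conversion"
    },
    {
      "identifier": "R2_c1",
      "name": "R2_c1",
      "reversible": false,
      "participants": [
        {
          "metabolite": "B",
          "role": "reactant",
          "compartment": "c1",
          "stoichiometry": 1
        },
        {
          "metabolite": "C",
          "role": "product",
          "compartment": "c1",
          "stoichiometry": 1
        }
      ],
      "processes": [
        "P1"
      ],
      "genes": [
        "gene_R2_c1"
      ],
      "references": {},
      "behavior": "conversion"
    },
    {
      "identifier": "R3_c1",
      "name": "R3_c1",
      "reversible": false,
      "participants": [
        {
          "metabolite": "C",
          "role": "reactant",
          "compartment": "c1",
          "stoichiometry": 1
        },
        {
          "metabolite": "D",
          "role": "product",
          "compartment": "c1",
          "stoichiometry": 1
        }
      ],
      "processes": [
        "P1"
      ],
      "genes": [
        "gene_R3_c1"
      ],
      "references": {},
      "behavior": "conversion"
    },
    {
      "identifier": "R4_c1",
      "name": "R4_c1",
      "reversible": false,
      "participants": [
        {
          "metabolite": "D",
          "role": "reactant",
          "compartment": "c1",
          "stoichiometry": 1
        },
        {
          "metabolite": "A",
          "role": "product",
          "compartment": "c1",
          "stoichiometry": 1
        }
      ],
      "processes": [
        "P1"
      ],
      "genes": [
        "gene_R4_c1"
      ],
      "references": {},
      "behavior": "conversion"
    },
    {
      "identifier": "R1_c2",
      "name": "R1_c2",
      "reversible": false,
      "participants": [
        {
          "metabolite": "A",
          "role": "reactant",
          "compartment": "c2",
          "stoichiometry": 1
        },
        {
          "metabolite": "B",
          "role": "product",
          "compartment": "c2",
          "stoichiometry": 1
        }
      ],
      "processes": [
        "P1"
      ],
      "genes": [
        "gene_R1_c2"
      ],
      "references": {},
      "behavior": "conversion"
    },
    {
      "identifier": "R2_c2",
      "name": "R2_c2",
      "reversible": false,
      "participants": [
        {
          "metabolite": "B",
          "role": "reactant",
          "compartment": "c2",
          "stoichiometry": 1
        },
        {
          "metabolite": "C",
          "role": "product",
          "compartment": "c2",
          "stoichiometry": 1
        }
      ],
      "processes": [
        "P1"
      ],
      "genes": [
        "gene_R2_c2"
      ],
      "references": {},
      "behavior": "conversion"
    },
    {
      "identifier": "R3_c2",
      "name": "R3_c2",
      "reversible": false,
      "participants": [
        {
          "metabolite": "C",
          "role": "reactant",
          "compartment": "c2",
          "stoichiometry": 1
        },
        {
          "metabolite": "D",
          "role": "product",
          "compartment": "c2",
          "stoichiometry": 1
        }
      ],
      "processes": [
        "P1"
      ],
      "genes": [
        "gene_R3_c2"
      ],
      "references": {},
      "behavior": "conversion"
    },
    {
      "identifier": "R4_c2",
      "name": "R4_c2",
      "reversible": false,
      "participants": [
        {
          "metabolite": "D",
          "role": "reactant",
          "compartment": "c2",
          "stoichiometry": 1
        },
        {
          "metabolite": "A",
          "role": "product",
          "compartment": "c2",
          "stoichiometry": 1
        }
      ],
      "processes": [
        "P1"
      ],
      "genes": [
        "gene_R4_c2"
      ],
      "references": {},
      "behavior": "conversion"
    },
    {
      "identifier": "T_A",
      "name": "T_A",
      "reversible": false,
      "participants": [
        {
          "metabolite": "A",
          "role": "reactant",
          "compartment": "c1",
          "stoichiometry": 1
        },
        {
          "metabolite": "A",
          "role": "product",
          "compartment": "c2",
          "stoichiometry": 1
        }
      ],
      "processes": [],
      "genes": [],
      "references": {},
      "behavior": "transport"
    },
    {
      "identifier": "T_B",
      "name": "T_B",
      "reversible": false,
      "participants": [
        {
          "metabolite": "B",
          "role": "reactant",
          "compartment": "c1",
          "stoichiometry": 1
        },
        {
          "metabolite": "B",
          "role": "product",
          "compartment": "c2",
          "stoichiometry": 1
        }
      ],
      "processes": [],
      "genes": [],
      "references": {},
      "behavior": "transport"
    },
    {
      "identifier": "T_C",
      "name": "T_C",
      "reversible": false,
      "participants": [
        {
          "metabolite": "C",
          "role": "reactant",
          "compartment": "c1",
          "stoichiometry": 1
        },
        {
          "metabolite": "C",
          "role": "product",
          "compartment": "c2",
          "stoichiometry": 1
        }
      ],
      "processes": [],
      "genes": [],
      "references": {},
      "behavior": "transport"
    },
    {
      "identifier": "T_D",
      "name": "T_D",
      "reversible": false,
      "participants": [
        {
          "metabolite": "D",
          "role": "reactant",
          "compartment": "c1",
          "stoichiometry": 1
        },
        {
          "metabolite": "D",
          "role": "product",
          "compartment": "c2",
          "stoichiometry": 1
        }
      ],
      "processes": [],
      "genes": [],
      "references": {},
      "behavior": "transport"
    }
  ],
  "boundary_compartment": null,
  "extracellular_compartment": null
}
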
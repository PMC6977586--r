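{
  "format": "metnets-model",
  "version": 1,
  "compartments": [
    {
      "identifier": "c1",
      "name": "compartment 1"
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
    },
    {
      "identifier": "H",
      "name": "hub H",
      "formula": "",
      "charge": 0,
      "references": {
        "pubchem": [
          "90005"
        ]
      }
    }
  ],
  "reactions": [
    {
      "identifier": "R1",
      "name": "R1",
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
        },
        {
          "metabolite": "H",
          "role": "product",
          "compartment": "c1",
          "stoichiometry": 1
        }
      ],
      "processes": [
        "P1"
      ],
      "genes": [
        "gene_R1"
      ],
      "references": {},
      "behavior": "conversion"
    },
    {
      "identifier": "R2",
      "name": "R2",
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
        },
        {
          "metabolite": "H",
          "role": "product",
          "compartment": "c1",
          "stoichiometry": 1
        }
      ],
      "processes": [
        "P1"
      ],
      "genes": [
        "gene_R2"
      ],
      "references": {},
      "behavior": "conversion"
    },
    {
      "identifier": "R3",
      "name": "R3",
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
        },
        {
          "metabolite": "H",
          "role": "product",
          "compartment": "c1",
          "stoichiometry": 1
        }
      ],
      "processes": [
        "P1"
      ],
      "genes": [
        "gene_R3"
      ],
      "references": {},
      "behavior": "conversion"
    },
    {
      "identifier": "R4",
      "name": "R4",
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
        },
        {
          "metabolite": "H",
          "role": "product",
          "compartment": "c1",
          "stoichiometry": 1
        }
      ],
      "processes": [
        "P1"
      ],
      "genes": [
        "gene_R4"
      ],
      "references": {},
      "behavior": "conversion"
    }
  ],
  "boundary_compartment": null,
  "extracellular_compartment": null
}
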
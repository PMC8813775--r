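{
  "format_version": 1,
  "id": "iita-cassava-ea-baseline",
  "pipeline_id": "iita-cassava-east-africa",
  "segment_ids": ["ea-fresh", "ea-flour"],
  "market_segments": [
    {
      "id": "ea-fresh",
      "client_features": {
        "farm_size": "smallholder",
        "geographical_region": "East Africa",
        "income": "low to middle"
      },
      "environment_features": {
        "altitude": "lowland",
        "prevailing_biotic_stresses": "cassava mosaic disease",
        "water_availability": "high rainfall"
      },
      "product_features": {
        "end_use": "fresh consumption",
        "maturity": "late",
        "mode_of_reproduction": "clonal",
        "shape": "long"
      }
    },
    {
      "id": "ea-flour",
      "client_features": {
        "farm_size": "smallholder",
        "geographical_region": "East Africa",
        "income": "low to middle"
      },
      "environment_features": {
        "altitude": "lowland",
        "prevailing_biotic_stresses": "cassava mosaic disease",
        "water_availability": "high rainfall"
      },
      "product_features": {
        "end_use": "high-quality flour",
        "maturity": "late",
        "mode_of_reproduction": "clonal",
        "shape": "long"
      }
    }
  ],
  "product_profiles": [
    {
      "segment_id": "ea-fresh",
      "traits": [
        {
          "name": "fresh_root_yield",
          "category": "output",
          "direction": "at_least",
          "bounds": [25],
          "unit": "t/ha"
        },
        {
          "name": "dry_matter_content",
          "category": "quality",
          "direction": "at_least",
          "bounds": [30],
          "unit": "%"
        },
        {
          "name": "cmd_severity",
          "category": "survival",
          "direction": "at_most",
          "bounds": [2],
          "unit": "score 1-5"
        },
        {
          "name": "plant_height",
          "category": "agronomic",
          "direction": "target_range",
          "bounds": [1.5, 2.5],
          "unit": "m"
        }
      ]
    }
  ],
  "stages": [
    {
      "name": "Crossing block",
      "label": "Crossing block",
      "year": [1, 1],
      "role": "crossing",
      "crossing": {
        "n_parents": 4,
        "n_crosses": 12,
        "n_progeny_per_cross": 136,
        "coupling_method": "random mating",
        "allow_reciprocals": true
      }
    },
    {
      "name": "Seedling nursery",
      "label": "Seedling nursery",
      "year": [1, 1],
      "role": "multiplication",
      "evaluation": {
        "n_locations": 1,
        "reps_per_location": 1,
        "design_label": "nursery beds",
        "plot_width": 1,
        "plot_length": 1,
        "plot_units": "m",
        "n_checks": 0,
        "other": {
          "cultivation_method": "seedbed",
          "plant_portion": "botanical seed"
        }
      },
      "selection": {
        "n_entries_in": 1632,
        "n_selected_out": 1632,
        "selection_method": "none",
        "surrogate_of_merit": "none",
        "recycling_source": false
      }
    },
    {
      "name": "CE",
      "label": "Stage 1 (CE)",
      "year": [2, 2],
      "role": "evaluation",
      "evaluation": {
        "n_locations": 1,
        "reps_per_location": 1,
        "design_label": "augmented",
        "plot_width": 1,
        "plot_length": 2.5,
        "plot_units": "m",
        "n_checks": 40,
        "other": {
          "plant_portion": "stem cutting"
        }
      },
      "selection": {
        "n_entries_in": 1632,
        "n_selected_out": 120,
        "selection_method": "phenotypic truncation",
        "surrogate_of_merit": "entry mean",
        "recycling_source": false
      }
    },
    {
      "name": "PYT",
      "label": "Stage 2 (PYT)",
      "year": [3, 3],
      "role": "evaluation",
      "evaluation": {
        "n_locations": 2,
        "reps_per_location": 2,
        "design_label": "RCBD",
        "plot_width": 2,
        "plot_length": 5,
        "plot_units": "m",
        "n_checks": 2,
        "other": {
          "plant_portion": "stem cutting"
        }
      },
      "selection": {
        "n_entries_in": 120,
        "n_selected_out": 64,
        "selection_method": "phenotypic truncation",
        "surrogate_of_merit": "entry mean",
        "recycling_source": true
      }
    },
    {
      "name": "AYT",
      "label": "Stage 3 (AYT)",
      "year": [4, 4],
      "role": "evaluation",
      "evaluation": {
        "n_locations": 2,
        "reps_per_location": 3,
        "design_label": "RCBD",
        "plot_width": 4,
        "plot_length": 5,
        "plot_units": "m",
        "n_checks": 2,
        "other": {
          "plant_portion": "stem cutting"
        }
      },
      "selection": {
        "n_entries_in": 64,
        "n_selected_out": 24,
        "selection_method": "phenotypic truncation",
        "surrogate_of_merit": "entry mean",
        "recycling_source": true
      }
    },
    {
      "name": "UYT1",
      "label": "Stage 4 (UYT) year 1",
      "year": [5, 5],
      "role": "evaluation",
      "evaluation": {
        "n_locations": 2,
        "reps_per_location": 3,
        "design_label": "RCBD",
        "plot_width": 4,
        "plot_length": 8,
        "plot_units": "m",
        "n_checks": 2,
        "other": {
          "plant_portion": "stem cutting"
        }
      },
      "selection": {
        "n_entries_in": 24,
        "n_selected_out": 24,
        "selection_method": "none",
        "surrogate_of_merit": "entry mean",
        "recycling_source": false
      }
    },
    {
      "name": "UYT2",
      "label": "Stage 4 (UYT) year 2",
      "year": [6, 6],
      "role": "evaluation",
      "evaluation": {
        "n_locations": 2,
        "reps_per_location": 3,
        "design_label": "RCBD",
        "plot_width": 4,
        "plot_length": 8,
        "plot_units": "m",
        "n_checks": 2,
        "other": {
          "plant_portion": "stem cutting"
        }
      },
      "selection": {
        "n_entries_in": 24,
        "n_selected_out": 24,
        "selection_method": "none",
        "surrogate_of_merit": "entry mean",
        "recycling_source": false
      }
    }
  ]
}
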
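{
  "$comment": "Field registry for aitcea model configurations. Sections and keys outside this registry are rejected by load_config(). Absent fields take the base-case defaults.",
  "sections": {
    "arms": {
      "type": "object of arm specifications keyed by arm name (five_grass, allergoid, symptomatic, or user-defined)",
      "fields": {
        "name": {"type": "string"},
        "label": {"type": "string"},
        "rtss": {"type": "number", "minimum": 0, "unit": "RTSS points (0-18 scale)"},
        "disc_y1": {"type": "number", "minimum": 0, "maximum": 1, "unit": "annual probability"},
        "disc_y2": {"type": "number", "minimum": 0, "maximum": 1, "unit": "annual probability"},
        "drug_cost_per_month": {"type": "number", "minimum": 0, "unit": "EUR/month"},
        "drug_cost_annual_fixed": {"type": "number", "minimum": 0, "unit": "EUR/year"},
        "visits_per_treatment_year": {"type": "number", "minimum": 0},
        "injections_per_treatment_year": {"type": "number", "minimum": 0},
        "supervised_first_dose": {"type": "boolean"},
        "diagnostic_in_year1": {"type": "boolean"}
      }
    },
    "clinical": {
      "fields": {
        "p_asthma_symptomatic": {"type": "number", "minimum": 0, "maximum": 1, "unit": "annual probability"},
        "rr_asthma_ait": {"type": "number", "minimum": 0, "unit": "relative risk"},
        "p_death_all": {"type": "number", "minimum": 0, "maximum": 1, "unit": "annual probability"},
        "p_death_asthma": {"type": "number", "minimum": 0, "maximum": 1, "unit": "annual probability; must be >= p_death_all"},
        "mean_age_entry": {"type": "number", "unit": "years"}
      }
    },
    "utility": {
      "fields": {
        "u_baseline": {"type": "number", "minimum": 0, "maximum": 1, "unit": "utility/year"},
        "k_rtss_slope": {"type": "number", "minimum": 0, "unit": "utility decrement per RTSS point during the season"},
        "season_months": {"type": "number", "minimum": 0, "maximum": 12, "unit": "months"},
        "asthma_decrement": {"type": "number", "minimum": 0, "unit": "utility/year"},
        "eq5d_ait": {"type": "number", "minimum": 0, "maximum": 1},
        "eq5d_symptomatic": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "costs": {
      "fields": {
        "c_specialist_visit": {"type": "number", "minimum": 0, "unit": "EUR"},
        "c_visit_additional": {"type": "number", "minimum": 0, "unit": "EUR"},
        "c_injection": {"type": "number", "minimum": 0, "unit": "EUR"},
        "c_diagnostics": {"type": "number", "minimum": 0, "unit": "EUR"},
        "c_asthma_annual": {"type": "number", "minimum": 0, "unit": "EUR/year"},
        "c_loratadine_ait": {"type": "number", "minimum": 0, "unit": "EUR/season"},
        "c_budesonide_ait": {"type": "number", "minimum": 0, "unit": "EUR/season"},
        "c_loratadine_sympt": {"type": "number", "minimum": 0, "unit": "EUR/season"},
        "c_budesonide_sympt": {"type": "number", "minimum": 0, "unit": "EUR/season"},
        "visits_per_year_off_treatment": {"type": "number", "minimum": 0},
        "c_labour_hour": {"type": "number", "minimum": 0, "unit": "EUR/hour"},
        "sick_days_symptomatic": {"type": "number", "minimum": 0, "unit": "days/season"},
        "sick_days_ait": {"type": "number", "minimum": 0, "unit": "days/season"},
        "productivity_saving_per_season": {"type": "number", "minimum": 0, "unit": "EUR per on-effect season"},
        "remuneration_unit_cost_tables": {"type": "object", "optional": true, "comment": "per-setting unit-cost overrides for the remuneration scenarios"}
      }
    },
    "settings": {
      "fields": {
        "horizon_years": {"type": "integer", "minimum": 3, "unit": "years"},
        "cycle_length": {"type": "number", "unit": "years"},
        "discount_rate": {"type": "number", "minimum": 0, "unit": "annual rate, costs and effects"},
        "wtp_grid": {"type": "array of numbers", "unit": "EUR/QALY"},
        "n_psa": {"type": "integer", "minimum": 1},
        "rng_seed": {"type": "integer"},
        "perspective": {"type": "string", "enum": ["payer", "societal"]},
        "efficacy_se_scale": {"type": "number", "minimum": 0, "comment": "SE of each efficacy (RTSS difference) parameter as a fraction of its absolute mean"}
      }
    }
  }
}
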
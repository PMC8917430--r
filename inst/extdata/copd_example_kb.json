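{
  "annotations": [
    {
      "feature": "days_since_last_acute_exacerbation_dx",
      "condition": {"interval": {"upper": 81.4}},
      "positively_correlated": true,
      "interpretation": "A recent acute exacerbation signals a need for better disease control.",
      "interventions": [
        "Provide education on disease self-management and schedule more frequent follow-ups",
        "Ensure use of appropriate maintenance medications",
        "Consider influenza shot, pneumonia vaccination, or smoking cessation support",
        "Assess the need for pulmonary rehabilitation or home care"
      ]
    },
    {
      "feature": "n_distinct_reliever_meds_past_year",
      "condition": {"interval": {"lower": 10}},
      "positively_correlated": true,
      "interpretation": "Heavy rescue-medication use suggests an ineffective regimen, poor adherence, or poor disease control.",
      "interventions": [
        "Simplify the regimen to once-a-day or combination formulations",
        "Provide education on correct inhaler technique",
        "Arrange a medication reconciliation review by a physician or pharmacist"
      ]
    },
    {
      "feature": "race",
      "condition": {"equals": "Black or African American"},
      "positively_correlated": true,
      "interpretation": "Poorer respiratory outcomes are more prevalent in this group, reflecting inequities in access and care.",
      "interventions": [
        "Ensure the patient has the needed resources and access to care",
        "Assess the need for social work or home care"
      ]
    },
    {
      "feature": "max_neutrophil_pct_past_year",
      "condition": {"interval": {"lower": 76.5}},
      "positively_correlated": true,
      "interpretation": "A high neutrophil percentage can indicate infection or physiologic distress.",
      "interventions": [
        "Evaluate the respiratory system, for example with radiographic imaging",
        "Consider diagnostic tests such as a viral panel or sputum culture"
      ]
    },
    {
      "feature": "former_smoker",
      "condition": {"equals": "yes"},
      "positively_correlated": false,
      "interpretation": "Former smoking status; not judged positively correlated with near-term severe exacerbations.",
      "interventions": []
    }
  ],
  "combinations": []
}
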
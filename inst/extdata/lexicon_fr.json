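{
  "sleep_disorder": {
    "terms": ["insomnie", "cauchemars", "reveils nocturnes"],
    "variants": ["insomnies", "cauchemar", "reveil nocturne",
                 "endormissement difficile"]
  },
  "loss_of_appetite": {
    "terms": ["perte d appetit", "anorexie", "inappetence"],
    "variants": ["appetit diminue"]
  },
  "stress_symptoms": {
    "terms": ["hypervigilance", "evitement", "sursauts",
              "souvenirs envahissants"],
    "variants": ["hypervigilante", "reviviscences"]
  },
  "pain_mention": {
    "terms": ["douleur", "douleurs", "cephalees", "endolori"],
    "variants": ["douloureux", "algies"]
  },
  "fear_mention": {
    "terms": ["angoisse", "crainte", "frayeur", "effroi"],
    "variants": ["peur", "apeure", "terrifie", "angoissee"]
  }
}
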
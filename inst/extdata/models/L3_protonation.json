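{
 "components": [
  "Ni",
  "L3",
  "H"
 ],
 "pKw": 13.73,
 "temperature": 25,
 "ionic_strength": 0.15,
 "species": [
  {
   "p": 0,
   "q": 1,
   "r": 1,
   "logbeta": 4.62,
   "sigma": 0.01,
   "refine": true
  },
  {
   "p": 0,
   "q": 1,
   "r": 2,
   "logbeta": 8.13,
   "sigma": 0.01,
   "refine": true
  },
  {
   "p": 0,
   "q": 1,
   "r": 3,
   "logbeta": 10.11,
   "sigma": 0.05,
   "refine": true
  }
 ],
 "description": "L3 protonation block (metal-free)"
}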
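{
 "components": [
  "Ni",
  "L1",
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
   "logbeta": 9.2,
   "sigma": 0.01,
   "refine": true
  },
  {
   "p": 0,
   "q": 1,
   "r": 2,
   "logbeta": 17.88,
   "sigma": 0.01,
   "refine": true
  },
  {
   "p": 0,
   "q": 1,
   "r": 3,
   "logbeta": 19.91,
   "sigma": 0.03,
   "refine": true
  }
 ],
 "description": "L1 protonation block (metal-free)"
}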
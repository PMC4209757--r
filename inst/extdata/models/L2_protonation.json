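{
 "components": [
  "Ni",
  "L2",
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
   "logbeta": 8.64,
   "sigma": 0.01,
   "refine": true
  },
  {
   "p": 0,
   "q": 1,
   "r": 2,
   "logbeta": 16.72,
   "sigma": 0.01,
   "refine": true
  },
  {
   "p": 0,
   "q": 1,
   "r": 3,
   "logbeta": 18.46,
   "sigma": 0.06,
   "refine": true
  }
 ],
 "description": "L2 protonation block (metal-free)"
}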
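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
   "refine": false
  },
  {
   "p": 0,
   "q": 1,
   "r": 2,
   "logbeta": 16.72,
   "sigma": 0.01,
   "refine": false
  },
  {
   "p": 0,
   "q": 1,
   "r": 3,
   "logbeta": 18.46,
   "sigma": 0.06,
   "refine": false
  },
  {
   "p": 1,
   "q": 1,
   "r": 0,
   "logbeta": 2.17,
   "sigma": 0.38,
   "refine": true
  },
  {
   "p": 1,
   "q": 1,
   "r": -1,
   "logbeta": -5.05,
   "sigma": 0.02,
   "refine": true
  },
  {
   "p": 1,
   "q": 1,
   "r": -2,
   "logbeta": -13.99,
   "sigma": 0.01,
   "refine": true
  }
 ],
 "description": "Ni(II)-L2 speciation model (model2)"
}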
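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
   "refine": false
  },
  {
   "p": 0,
   "q": 1,
   "r": 2,
   "logbeta": 17.88,
   "sigma": 0.01,
   "refine": false
  },
  {
   "p": 0,
   "q": 1,
   "r": 3,
   "logbeta": 19.91,
   "sigma": 0.03,
   "refine": false
  },
  {
   "p": 1,
   "q": 1,
   "r": 1,
   "logbeta": 13.88,
   "sigma": 0.01,
   "refine": true
  },
  {
   "p": 1,
   "q": 1,
   "r": -1,
   "logbeta": -1.82,
   "sigma": 0.02,
   "refine": true
  },
  {
   "p": 1,
   "q": 1,
   "r": -2,
   "logbeta": -10.92,
   "sigma": 0.02,
   "refine": true
  }
 ],
 "description": "Ni(II)-L1 speciation model (model1)"
}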
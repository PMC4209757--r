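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
   "r": 1,
   "logbeta": 11.22,
   "sigma": 0.07,
   "refine": true
  },
  {
   "p": 1,
   "q": 1,
   "r": -1,
   "logbeta": -4.99,
   "sigma": 0.02,
   "refine": true
  },
  {
   "p": 1,
   "q": 1,
   "r": -2,
   "logbeta": -13.94,
   "sigma": 0.01,
   "refine": true
  }
 ],
 "description": "Ni(II)-L2 speciation model (model1)"
}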
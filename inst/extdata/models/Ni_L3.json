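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
   "refine": false
  },
  {
   "p": 0,
   "q": 1,
   "r": 2,
   "logbeta": 8.13,
   "sigma": 0.01,
   "refine": false
  },
  {
   "p": 0,
   "q": 1,
   "r": 3,
   "logbeta": 10.11,
   "sigma": 0.05,
   "refine": false
  },
  {
   "p": 1,
   "q": 1,
   "r": 1,
   "logbeta": 7.7,
   "sigma": 0.08,
   "refine": true
  },
  {
   "p": 1,
   "q": 1,
   "r": 0,
   "logbeta": 3.69,
   "sigma": 0.04,
   "refine": true
  },
  {
   "p": 1,
   "q": 1,
   "r": -1,
   "logbeta": -2.65,
   "sigma": 0.04,
   "refine": true
  },
  {
   "p": 1,
   "q": 1,
   "r": -2,
   "logbeta": -9.84,
   "sigma": 0.03,
   "refine": true
  }
 ],
 "description": "Ni(II)-L3 speciation model"
}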
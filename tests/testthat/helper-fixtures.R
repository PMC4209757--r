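# Shared fixtures built once per test run (all generated in code).

# simple hydroxide-only model (inert metal, no ligand chemistry)
water_model <- eq_model(eq_species(0, 0, -1, -13.73))

# monoprotic ligand, pKa 9.20
monoprotic_model <- eq_model(eq_species(0, 1, 1, 9.20))

# ligand (pKa 9) plus one strong 1:1 complex
ml_model <- eq_model(rbind(eq_species(0, 1, 1, 9.0),
                           eq_species(1, 1, 0, 12.0, refine = TRUE)))

# zero-noise Ni(II)-L1 model-1 study curves (3 ratios), reused widely
l1_curves_clean <- generate_study_dataset("L1", noise = FALSE)
l1_model <- example_model("Ni_L1_model1")

# clean strong-acid vs NaOH titration for calibration / Gran tests
strong_acid_curve <- simulate_titration(
  water_model, titration_protocol(n_acid = 2.5e-4, increment = 0.02))
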
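# Shared fixtures: the two literature spheres, the bundled solvent library,
# the monosolvent solubility tables, and small constructors used across
# tests.

resveratrol_sphere <- function() {
  hansen_sphere(12.2, 9.9, 12.7, 10.1, solute = "trans-resveratrol",
                provenance = "literature")
}

hesperetin_sphere <- function() {
  hansen_sphere(12.7, 10.3, 12.5, 10.7, solute = "hesperetin",
                provenance = "literature")
}

builtin_lib <- function() load_solvent_library()

solvent_hsp <- function(name, lib = builtin_lib()) {
  lookup_solvent(lib, name)$hsp
}

resv_measurements <- function() {
  read_solubility(system.file("extdata", "solubility_resveratrol_synthetic.csv",
                              package = "hspfit"))
}

hesp_measurements <- function() {
  read_solubility(system.file("extdata", "solubility_hesperetin_synthetic.csv",
                              package = "hspfit"))
}

# good-solvent sets reported for the two polyphenols
resv_good_set <- function() {
  sort(c("ethanol", "methanol", "1-propanol", "acetone", "methyl ethyl ketone",
         "methyl isobutyl ketone", "ethyl lactate", "ethyl acetate"))
}

hesp_good_set <- function() {
  sort(c("methanol", "acetone", "methyl ethyl ketone",
         "methyl isobutyl ketone", "ethyl lactate", "n-propyl acetate"))
}

# in-memory solvent library from a coordinate matrix
make_lib <- function(names, mat) {
  df <- data.frame(name = names, delta_d = mat[, 1], delta_p = mat[, 2],
                   delta_h = mat[, 3], synonyms = "", source = "test",
                   stringsAsFactors = FALSE)
  attr(df, "version") <- "test"
  class(df) <- c("solvent_library", "data.frame")
  df
}

random_hsp <- function() hsp(runif(1, 5, 25), runif(1, 0, 25), runif(1, 0, 25))

# replicate-seed policy for recovery experiments: first seed in
# {r, r+100, r+200, ...} whose dataset has both classes
fittable_dataset <- function(r, label_noise = 0) {
  s <- r
  repeat {
    d <- generate_dataset(synthetic_config(seed = s, label_noise = label_noise))
    if (any(d$labels$label == "good") && any(d$labels$label == "bad")) return(d)
    s <- s + 100
  }
}
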
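# shared fixtures built in code

# random coefficient tables for property tests
random_systems <- function(n, seed) {
  set.seed(seed)
  data.frame(system_id = paste0("sys", seq_len(n)),
             category = "pampa",
             c = stats::rnorm(n),
             e = stats::rnorm(n, 0, 0.3),
             s = stats::rnorm(n, -1, 0.6),
             a = stats::rnorm(n, -1.5, 1),
             b = stats::rnorm(n, -2.5, 1),
             v = stats::runif(n, 0.2, 5),
             stringsAsFactors = FALSE)
}

# the nine PAMPA membranes / five biological processes from the
# packaged compilation
pampa_nine <- function() {
  sys <- pampa_systems()
  sys[sys$category == "pampa", ]
}

bio_five <- function() {
  sys <- pampa_systems()
  sys[sys$category == "biological", ]
}
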
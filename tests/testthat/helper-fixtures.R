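# Shared fixture builders: everything is generated in code at test time.

# deterministic random protein sequence
rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(ire1cld:::AA_LETTERS, n, replace = TRUE), collapse = "")
}

# small labeled peak list
toy_peaks <- function() {
  data.frame(
    label = c("I52", "I124", "I128", "I263", "L186I"),
    w_C = c(10.2, 11.8, 12.5, 13.1, 14.0),
    w_H = c(0.55, 0.71, 0.62, 0.88, 0.95),
    height = c(1.0, 1.4, 0.9, 1.2, 2.0))
}

# two parallel helix chains offset along x
helix_dimer <- function(n = 40, offset = 10) {
  h1 <- gen_helix(helix_spec(n), chain = "A")
  h2 <- gen_helix(helix_spec(n), chain = "B")
  h2$x <- h2$x + offset
  structure_model(rbind(h1, h2))
}

# titration grid helper: n log-spaced points between conc limits (uM)
log_grid <- function(lo, hi, n = 16) {
  seq(log10(lo), log10(hi), length.out = n)
}
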
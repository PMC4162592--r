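# shared helpers for the test suite

empty3 <- matrix(integer(0), 0, 3)
empty4 <- matrix(integer(0), 0, 4)

# raw SAW counts through both engines
saw_both <- function(nsteps, closed = FALSE, target = c(0L, 0L, 0L),
                     blocked = empty3, mm = empty4, fixed = integer(0)) {
  c(production = vfold:::vf_saw_count_cpp(nsteps, closed, as.integer(target),
                                          blocked, mm, as.integer(fixed)),
    oracle = vfold:::vf_saw_count_oracle_cpp(nsteps, closed, as.integer(target),
                                             blocked, mm, as.integer(fixed)))
}

# conformation counts for a loop through both engines
loop_both <- function(loop_type, sizes, mm = NULL, cap = 8) {
  list(production = enumerate_loop(loop_type, sizes, cap, mm,
                                   engine = "production"),
       oracle = enumerate_loop(loop_type, sizes, cap, mm, engine = "oracle"))
}

# independent per-helix two-state melting temperature from the parameter
# tables: Tm = sum(dH) / (sum(dS_stack) + R * S_loop)
helix_two_state_tm <- function(seq, pairs, loop_len,
                               params = energy_params("turner04"),
                               entropies = loop_entropy_table()) {
  ch <- strsplit(as.character(seq), "")[[1]]
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  dH <- 0; dS <- 0
  for (t in seq_len(nrow(pairs) - 1)) {
    po <- paste0(ch[pairs[t, 1]], ch[pairs[t, 2]])
    pi <- paste0(ch[pairs[t + 1, 1]], ch[pairs[t + 1, 2]])
    rev2 <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
    dH <- dH + params$stack$dH[po, rev2(pi)]
    dS <- dS + params$stack$dS[po, rev2(pi)]
  }
  S_loop <- extrapolate_entropy(entropies, "hairpin", loop_len)$entropy
  dS <- dS + params$gas_constant * S_loop
  dH / dS - 273.15
}
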
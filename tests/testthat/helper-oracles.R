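# independent O(n^2) pair-enumeration oracle for the concordance index
brute_force_c <- function(risk, entry, exit, died) {
  conc <- 0; comp <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !died[i]) next
    t <- exit[i]
    comparable <- entry[j] < t && (exit[j] > t || (exit[j] == t && !died[j]))
    if (!comparable) next
    comp <- comp + 1
    conc <- conc + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
  }
  conc / comp
}
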
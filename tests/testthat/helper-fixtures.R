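# Shared fixtures: one deterministic locus reused across tests.
test_locus <- function() synthetic_locus(seed = 42L)

# Independent IUPAC superposition oracle (simple per-position lookup).
oracle_superpose <- function(a, b) {
  code <- c(A = "A", C = "C", G = "G", T = "T",
            AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- max(length(ca), length(cb))
  out <- character(n)
  for (i in seq_len(n)) {
    s <- sort(unique(c(ca[i][!is.na(ca[i])], cb[i][!is.na(cb[i])])))
    out[i] <- code[[paste(s, collapse = "")]]
  }
  paste(out, collapse = "")
}

expect_events_equal <- function(ev1, ev2) {
  expect_identical(event_signature(ev1), event_signature(ev2))
}
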
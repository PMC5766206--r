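# Shared helpers: deterministic random sequences and a default toy model.

toy <- toy_energy_model()

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

# lexicographically smallest string under C collation (ASCII)
lex_min <- function(x) sort(x, method = "radix")[1]

# the bundled planted chain (computed once; used across test files)
fixture_au <- generate_chain(alphabet = "AU")
fixture_gc <- generate_chain(alphabet = "GC")
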
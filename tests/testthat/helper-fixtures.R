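# Shared fixtures: a deterministic hand-built switch and a cached
# generated library so expensive generation runs once per test session.

toy_switch <- function(name = "toy", reporter = "green") {
  # AC-only toehold (structure-free by construction); mixed stem
  switch_part(
    name,
    toehold_seq = "ACACCAACACCA",
    stem_bottom = "GAUCCGUAAGCUGGAUCC",
    stem_top = rna_revcomp("GAUCCGUAAGCUGGAUCC"),
    loop_seq = "ACAGGAGGCAA",
    linker_seq = "AUGACACCAACACCAACACCA",
    start_codon_offset = 0L,
    reporter = reporter
  )
}

.fixture_cache <- new.env(parent = emptyenv())

fixture_library <- function(n = 4, seed = 11) {
  key <- paste0("lib_", n, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      make_switch_library(fixture_spec(n_switches = n, seed = seed))
  }
  .fixture_cache[[key]]
}

compiled_circuit <- function(circ, n = 4, seed = 11, rng_seed = 5, ...) {
  key <- paste0("nl_", circ, "_", n, "_", seed, "_", rng_seed)
  if (is.null(.fixture_cache[[key]])) {
    nl <- compile_circuit(logic_spec(circ), fixture_library(n, seed),
                          design_config(rng_seed = rng_seed), ...)
    .fixture_cache[[key]] <- assign_plasmids(wire_inducers(nl))
  }
  .fixture_cache[[key]]
}

expect_rows_match_logic <- function(tt, logic_fun, channels) {
  for (r in seq_len(nrow(tt))) {
    a <- tt[r, 1] == 1
    b <- if (ncol(tt) > 1 && is.numeric(tt[r, 2])) tt[r, 2] == 1 else NA
    want <- logic_fun(a, b)
    got <- vapply(channels, function(ch) tt[[paste0("call_", ch)]][r],
                  logical(1))
    expect_equal(unname(got), unname(want),
                 info = sprintf("row %d (A=%d B=%s)", r, a, b))
  }
}
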
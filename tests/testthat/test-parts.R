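test_that("a well-formed switch passes validation; defects are reported", {
  sw <- toy_switch()
  rep <- validate_switch(sw)
  expect_true(rep$valid)
  expect_true(all(rep$checks$pass))

  # reversed (not complemented) stem strand fails the stem check
  broken <- sw
  broken$stem_top <- paste(rev(strsplit(sw$stem_bottom, "")[[1]]),
                           collapse = "")
  rep2 <- validate_switch(broken)
  expect_false(rep2$valid)
  expect_false(rep2$checks$pass[rep2$checks$check == "stem_complementarity"])

  # duplicated RBS in the loop fails the RBS-count check
  dup <- sw
  dup$loop_seq <- "AGGAGGAGGAGG"  # contains AGGAGG twice
  rep3 <- validate_switch(dup)
  expect_false(rep3$checks$pass[rep3$checks$check == "rbs_single"])
  expect_equal(count_rbs <- sum(gregexpr("AGGAGG", dup$loop_seq,
                                         fixed = TRUE)[[1]] > 0), 2)

  expect_error(switch_part("bad", "ACXG", "ACGU", "ACGU", "AGGAGG",
                           "AUG"), "invalid RNA")
})

test_that("trigger/antisense assembly and disassembly are inverse", {
  tr <- trigger_rna("T1", core_seq = "GAUCCGUA", overhang5 = "ACCAA",
                    overhang3 = "CCAAC",
                    bulges = data.frame(position = c(5L, 14L),
                                        base = c("A", "C")))
  full <- rna_sequence(tr)
  expect_equal(nchar(full), 5 + 1 + 8 + 1 + 5)
  comp <- disassemble_rna(full, 5, 8, tr$bulges)
  expect_equal(comp$overhang5, tr$overhang5)
  expect_equal(comp$core_seq, tr$core_seq)
  expect_equal(comp$overhang3, tr$overhang3)

  # property: round trip over random components
  withr::with_seed(42, {
    for (rep in 1:100) {
      o5 <- random_rna_str(sample(0:15, 1))
      o3 <- random_rna_str(sample(0:15, 1))
      core <- random_rna_str(sample(10:30, 1))
      b <- data.frame(position = integer(0), base = character(0))
      if (nchar(o5) > 0 && runif(1) < 0.5) {
        b <- rbind(b, data.frame(position = nchar(o5), base = "A"))
      }
      if (nchar(o3) > 0 && runif(1) < 0.5) {
        b <- rbind(b, data.frame(
          position = nchar(o5) + nrow(b) + nchar(core), base = "C"))
      }
      tr <- trigger_rna("t", core, o5, o3, bulges = b)
      comp <- disassemble_rna(rna_sequence(tr), nchar(o5), nchar(core),
                              b)
      expect_identical(comp[c("overhang5", "core_seq", "overhang3")],
                       list(overhang5 = o5, core_seq = core,
                            overhang3 = o3))
    }
  })
})

test_that("part libraries round-trip through FASTA bit-exactly", {
  lib <- fixture_library(n = 3)
  cfg <- design_config(rng_seed = 3)
  tr <- derive_trigger(lib[[1]], cfg, avoid = switch_sequence(lib[[2]]))
  an <- derive_antisense(tr, cfg)
  parts <- c(lib, list(tr, an))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_part_library(parts, path)
  back <- load_part_library(path, quiet = TRUE)
  expect_length(back, length(parts))
  for (k in seq_along(parts)) {
    orig <- parts[[k]]
    got <- back[[orig$name]]
    expect_identical(class(got), class(orig))
    for (f in setdiff(names(orig), c("bulges", "cognate_switch",
                                     "input_bit"))) {
      expect_identical(got[[f]], orig[[f]])
    }
    if (!is.null(orig$bulges)) {
      expect_equal(got$bulges$position, orig$bulges$position)
      expect_equal(got$bulges$base, orig$bulges$base)
    }
  }
})

test_that("FASTA loader reports malformed and unannotated records", {
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1 role=switch toehold_len=2 stem_len=2 loop_len=2 linker_len=2",
               "ACXGACGUAC"), bad)
  expect_error(load_part_library(bad), "r1.*non-ACGU")

  norole <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r2", "ACGUACGU"), norole)
  expect_error(load_part_library(norole), "missing role")

  expect_error(load_part_library("/nonexistent/x.fasta"), "not found")
})

test_that("DNA input is transliterated to RNA on load", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">d role=trigger overhang5_len=0 core_len=8 operator=none",
               "GATCCGTA"), p)
  expect_message(lib <- load_part_library(p, quiet = FALSE),
                 "transliterated")
  expect_equal(lib$d$core_seq, "GAUCCGUA")
})

test_that("the generator's parts always satisfy the validator", {
  # generator-validator consistency over many random parts
  libs <- lapply(1:25, function(s) {
    make_switch_library(fixture_spec(n_switches = 4, seed = 1000 + s))
  })
  parts <- unlist(libs, recursive = FALSE)
  expect_gte(length(parts), 100)
  ok <- vapply(parts, function(p) validate_switch(p)$valid, logical(1))
  expect_true(all(ok))
})

test_that("netlists reject dangling or undeclared edges", {
  sw <- toy_switch()
  tr <- trigger_rna("T1", core_seq = rna_revcomp(sensing_domain(sw)))
  an <- antisense_rna("A1", target_trigger = "T1",
                      core_seq = sensing_domain(sw))
  edges <- data.frame(from = "T1", to = "ghost", type = "activates",
                      sensor = 1L)
  expect_error(circuit_netlist(list(sw), list(tr), list(an), edges),
               "unknown species")
  edges2 <- rbind(
    data.frame(from = "T1", to = "toy", type = "activates", sensor = 1L),
    data.frame(from = "A1", to = "T1", type = "annihilates",
               sensor = NA_integer_))
  nl <- circuit_netlist(list(sw), list(tr), list(an), edges2)
  expect_s3_class(nl, "circuit_netlist")
  # an antisense may not annihilate a trigger it is not declared against
  an2 <- antisense_rna("A1", target_trigger = "T9",
                       core_seq = sensing_domain(sw))
  expect_error(circuit_netlist(list(sw), list(tr), list(an2), edges2),
               "declared against")
})

test_that("netlists serialise to JSON and GenBank-style cassettes", {
  nl <- compiled_circuit("XOR")
  jpath <- withr::local_tempfile(fileext = ".json")
  write_netlist_json(nl, jpath)
  back <- read_netlist_json(jpath)
  expect_equal(names(back$triggers), names(nl$triggers))
  expect_equal(vapply(back$triggers, rna_sequence, character(1)),
               vapply(nl$triggers, rna_sequence, character(1)))
  expect_equal(back$edges, nl$edges)
  expect_equal(back$plasmids, nl$plasmids)
  expect_equal(back$inducer_map, nl$inducer_map)

  gpath <- withr::local_tempfile(fileext = ".gb")
  write_cassette_genbank(nl, gpath)
  txt <- readLines(gpath)
  expect_equal(sum(grepl("^LOCUS", txt)),
               length(nl$switches) + length(nl$triggers) +
                 length(nl$antisenses))
  expect_true(any(grepl("toehold", txt)))
  expect_true(any(grepl("5' overhang|core", txt)))
  expect_true(any(grepl("^ORIGIN", txt)))
})

test_that("YAML sidecar metadata supplements FASTA headers", {
  lib <- fixture_library(n = 2)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_part_library(lib, path, sidecar = TRUE)
  expect_true(file.exists(paste0(path, ".yaml")))
  # strip the header tokens; the sidecar alone must reconstruct parts
  lines <- readLines(path)
  lines <- sub("^>(\\S+).*$", ">\\1", lines)
  writeLines(lines, path)
  back <- load_part_library(path, quiet = TRUE)
  expect_identical(vapply(back, switch_sequence, character(1)),
                   vapply(lib, switch_sequence, character(1)))
  expect_identical(back[[1]]$toehold_seq, lib[[1]]$toehold_seq)
})
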
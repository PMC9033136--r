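test_that("gate netlists have the prescribed architecture", {
  lib <- fixture_library()
  cfg <- design_config(rng_seed = 5)

  xor <- compile_gate(logic_spec("XOR"), lib, cfg)
  expect_length(xor$switches, 1)
  expect_s3_class(xor$switches[[1]], "concatenated_switch")
  expect_length(xor$switches[[1]]$sensors, 2)
  expect_equal(nchar(xor$switches[[1]]$linker_between_sensors), 9)
  expect_length(xor$triggers, 2)
  expect_length(xor$antisenses, 2)
  expect_equal(nrow(xor$edges), 4)
  expect_equal(sum(xor$edges$type == "activates"), 2)
  expect_equal(sum(xor$edges$type == "annihilates"), 2)

  org <- compile_gate(logic_spec("OR"), lib, cfg)
  expect_length(org$antisenses, 0)
  expect_equal(nchar(org$switches[[1]]$linker_between_sensors), 9)

  nim <- compile_gate(logic_spec("NIMPLY"), lib, cfg)
  expect_equal(sum(nim$edges$type == "activates"), 1)
  expect_equal(sum(nim$edges$type == "annihilates"), 1)

  nand <- compile_gate(logic_spec("NAND"), lib, cfg)
  expect_true(all(vapply(nand$triggers, function(t) t$operator,
                         character(1)) == "constitutive"))

  expect_error(compile_gate(logic_spec("XOR"), lib[1], cfg),
               "insufficient orthogonal parts")
})

test_that("two-output circuits compose sub-gates on shared inputs", {
  ha <- compiled_circuit("HALF_ADDER")
  hs <- compiled_circuit("HALF_SUBTRACTOR")
  fey <- compiled_circuit("FEYNMAN")

  # half adder: AND arm on the red channel, no antisense there
  expect_length(ha$switches, 2)
  and_sw <- ha$switches[[2]]
  expect_equal(and_sw$logic, "AND")
  expect_equal(ha$reporters[[and_sw$name]], "red")

  # half subtractor: red channel carries exactly one antisense (NIMPLY)
  expect_length(hs$antisenses, 3)
  red_ann <- hs$edges[hs$edges$type == "annihilates" &
                        hs$edges$to == "T3", ]
  expect_equal(nrow(red_ann), 1)

  # identical green-channel (XOR) sub-netlists across the calculators
  expect_identical(lapply(ha$triggers[c("T1", "T2")], rna_sequence),
                   lapply(hs$triggers[c("T1", "T2")], rna_sequence))
  expect_identical(lapply(ha$antisenses[c("A1", "A2")], rna_sequence),
                   lapply(hs$antisenses[c("A1", "A2")], rna_sequence))
  expect_identical(rna_sequence(ha$switches[[1]]),
                   rna_sequence(hs$switches[[1]]))

  # Feynman BUFFER arm: no antisense, trigger without overhangs
  expect_length(fey$antisenses, 2)  # only the XOR arm
  t3 <- fey$triggers[["T3"]]
  expect_equal(t3$overhang5, "")
  expect_equal(t3$overhang3, "")
  p_ann <- fey$edges[fey$edges$type == "annihilates" &
                       fey$edges$to == "T3", ]
  expect_equal(nrow(p_ann), 0)

  expect_error(compile_circuit(logic_spec("HALF_ADDER"),
                               fixture_library()[1:3]),
               "insufficient orthogonal parts")
  expect_error(logic_spec("HALF_ADDER", outputs = c("green", "green")),
               "reporter collision")
})

test_that("inducer wiring follows the cross-induction rule", {
  xor <- compiled_circuit("XOR")
  ops <- c(vapply(xor$triggers, function(t) t$operator, character(1)),
           vapply(xor$antisenses, function(a) a$operator, character(1)))
  # IPTG/lac drives T1 and A2; aTc/tet drives T2 and A1
  expect_equal(ops[["T1"]], "lac")
  expect_equal(ops[["A2"]], "lac")
  expect_equal(ops[["T2"]], "tet")
  expect_equal(ops[["A1"]], "tet")
  expect_equal(xor$inducer_map, c(IPTG = "lac", aTc = "tet"))

  # NAND keeps constitutive triggers but wires antisenses as in XOR
  nand <- compiled_circuit("NAND")
  expect_equal(vapply(nand$triggers, function(t) t$operator,
                      character(1)),
               c(T1 = "constitutive", T2 = "constitutive"))
  expect_equal(vapply(nand$antisenses, function(a) a$operator,
                      character(1)),
               c(A1 = "tet", A2 = "lac"))

  # single-input BUFFER: its trigger carries the input operator
  buf <- compile_gate(logic_spec("BUFFER", inputs = "IPTG"),
                      fixture_library()[1], design_config(rng_seed = 5))
  buf <- wire_inducers(buf, c(IPTG = "A"))
  expect_equal(buf$triggers[["T1"]]$operator, "lac")

  # arity mismatch
  nl <- compile_gate(logic_spec("XOR"), fixture_library(),
                     design_config(rng_seed = 5))
  expect_error(wire_inducers(nl, c(IPTG = "A")), "does not cover")
})

test_that("plasmid copy levels follow the low/medium/high architecture", {
  xor <- compiled_circuit("XOR")
  expect_equal(unname(xor$plasmids[names(xor$switches)]), "low")
  expect_equal(unname(xor$plasmids[names(xor$triggers)]),
               rep("medium", 2))
  expect_equal(unname(xor$plasmids[names(xor$antisenses)]),
               rep("high", 2))

  orn <- assign_plasmids(compile_gate(logic_spec("OR"), fixture_library(),
                                      design_config(rng_seed = 5)))
  expect_false(any(orn$plasmids == "high"))

  ov <- assign_plasmids(compiled_circuit("XOR"),
                        override = c(T1 = "high"))
  expect_equal(unname(ov$plasmids[["T1"]]), "high")
  expect_error(assign_plasmids(xor, override = c(T1 = "giant")),
               "unknown copy level")
})

test_that("edge-level symbolic evaluation matches Boolean definitions", {
  truth <- list(
    XOR = function(a, b) c(green = xor(a, b)),
    NAND = function(a, b) c(green = !(a && b)),
    HALF_ADDER = function(a, b) c(green = xor(a, b), red = a && b),
    HALF_SUBTRACTOR = function(a, b) c(green = xor(a, b),
                                       red = !a && b),
    FEYNMAN = function(a, b) c(green = xor(a, b), red = a)
  )
  for (circ in names(truth)) {
    nl <- compiled_circuit(circ)
    for (a in c(FALSE, TRUE)) {
      for (b in c(FALSE, TRUE)) {
        got <- eval_netlist_boolean(nl, c(A = a, B = b))
        want <- truth[[circ]](a, b)
        expect_equal(got[names(want)], want,
                     info = sprintf("%s A=%d B=%d", circ, a, b))
      }
    }
  }
  # Feynman reversibility: (A,B) -> (P,Q) is a bijection
  fey <- compiled_circuit("FEYNMAN")
  outs <- apply(expand.grid(A = c(FALSE, TRUE), B = c(FALSE, TRUE)), 1,
                function(x) {
                  paste(eval_netlist_boolean(fey, c(A = x[["A"]],
                                                    B = x[["B"]])),
                        collapse = "")
                })
  expect_equal(anyDuplicated(outs), 0)
})

test_that("compilation is deterministic given library and seed", {
  lib <- fixture_library()
  cfg <- design_config(rng_seed = 5)
  a <- compile_circuit(logic_spec("HALF_SUBTRACTOR"), lib, cfg)
  b <- compile_circuit(logic_spec("HALF_SUBTRACTOR"), lib, cfg)
  expect_identical(vapply(a$triggers, rna_sequence, character(1)),
                   vapply(b$triggers, rna_sequence, character(1)))
  expect_identical(vapply(a$antisenses, rna_sequence, character(1)),
                   vapply(b$antisenses, rna_sequence, character(1)))
})

test_that("single gates evaluate to their Boolean functions", {
  lib <- fixture_library()
  cfg <- design_config(rng_seed = 5)
  single <- list(
    BUFFER = list(n_in = 1, f = function(a, b) a),
    NOT = list(n_in = 1, f = function(a, b) !a),
    OR = list(n_in = 2, f = function(a, b) a || b),
    AND = list(n_in = 2, f = function(a, b) a && b),
    NIMPLY = list(n_in = 2, f = function(a, b) a && !b)
  )
  for (g in names(single)) {
    inputs <- c("IPTG", "aTc")[seq_len(single[[g]]$n_in)]
    nl <- compile_gate(logic_spec(g, inputs = inputs), lib, cfg)
    for (a in c(FALSE, TRUE)) {
      for (b in c(FALSE, TRUE)) {
        got <- eval_netlist_boolean(nl, c(A = a, B = b))
        expect_equal(unname(got["green"]), single[[g]]$f(a, b),
                     info = sprintf("%s A=%d B=%d", g, a, b))
      }
    }
  }
})
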
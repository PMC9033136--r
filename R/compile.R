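#' Specify a logic function to compile
#'
#' @param circuit one of \code{"BUFFER"}, \code{"NOT"}, \code{"OR"},
#'   \code{"AND"}, \code{"NIMPLY"}, \code{"XOR"}, \code{"NAND"},
#'   \code{"HALF_ADDER"}, \code{"HALF_SUBTRACTOR"}, \code{"FEYNMAN"}.
#' @param inputs ordered inducer names mapped to input bits A, B, ...
#'   (default IPTG -> A, aTc -> B).
#' @param outputs ordered reporter channels; one for single gates, two
#'   for the two-output calculators.
#' @return An object of class \code{logic_spec}.
#' @export
logic_spec <- function(circuit, inputs = c("IPTG", "aTc"),
                       outputs = NULL) {
  circuit <- match.arg(toupper(circuit),
                       c("BUFFER", "NOT", "OR", "AND", "NIMPLY", "XOR",
                         "NAND", "HALF_ADDER", "HALF_SUBTRACTOR",
                         "FEYNMAN"))
  n_in <- if (circuit %in% c("BUFFER", "NOT")) 1L else 2L
  n_out <- if (circuit %in% c("HALF_ADDER", "HALF_SUBTRACTOR", "FEYNMAN")) {
    2L
  } else {
    1L
  }
  if (length(inputs) > n_in) inputs <- inputs[seq_len(n_in)]
  if (length(inputs) != n_in) {
    stop(sprintf("%s takes %d input(s), got %d", circuit, n_in,
                 length(inputs)), call. = FALSE)
  }
  if (is.null(outputs)) {
    outputs <- c("green", "red")[seq_len(n_out)]
  }
  if (length(outputs) != n_out) {
    stop(sprintf("%s has %d output(s), got %d", circuit, n_out,
                 length(outputs)), call. = FALSE)
  }
  if (anyDuplicated(outputs)) {
    stop("reporter collision: outputs must use distinct channels",
         call. = FALSE)
  }
  structure(list(circuit = circuit, inputs = inputs, outputs = outputs),
            class = "logic_spec")
}

# internal builder state: sequential T/A numbering and an avoid-list of
# everything designed so far
new_build <- function(library, model) {
  env <- new.env(parent = emptyenv())
  env$t_idx <- 0L
  env$a_idx <- 0L
  env$avoid <- vapply(library, switch_sequence, character(1))
  env$model <- model
  env
}

build_trigger <- function(build, sw, cfg, bit, overhang_mode = NULL) {
  build$t_idx <- build$t_idx + 1L
  cfg2 <- cfg
  if (!is.null(overhang_mode)) cfg2$trigger_overhang_mode <- overhang_mode
  cfg2$rng_seed <- cfg$rng_seed + 1000L * build$t_idx
  tr <- derive_trigger(sw, cfg2, build$model, avoid = build$avoid,
                       name = paste0("T", build$t_idx))
  tr$input_bit <- bit
  build$avoid <- c(build$avoid, rna_sequence(tr))
  tr
}

build_antisense <- function(build, trigger, cfg, bit) {
  build$a_idx <- build$a_idx + 1L
  cfg2 <- cfg
  cfg2$rng_seed <- cfg$rng_seed + 2000L * build$a_idx
  an <- derive_antisense(trigger, cfg2, build$model, avoid = build$avoid,
                         name = paste0("A", sub("^T", "", trigger$name)))
  an$input_bit <- bit
  build$avoid <- c(build$avoid, rna_sequence(an))
  an
}

edge_row <- function(from, to, type, sensor = NA_integer_) {
  data.frame(from = from, to = to, type = type,
             sensor = as.integer(sensor), stringsAsFactors = FALSE)
}

#' Compile a single logic gate into a circuit netlist
#'
#' Realises the gate architectures of the platform: a NIMPLY gate is
#' one switch + trigger + cognate antisense; an OR gate concatenates
#' two orthogonal switch sensors with a 9-nt linker; an XOR gate is two
#' NIMPLY gates on a concatenated OR switch
#' (A XOR B = (A NIMPLY B) OR (B NIMPLY A)); an AND gate is a
#' black-box two-trigger sensor; NAND is the XOR netlist with both
#' triggers made constitutive.
#'
#' @param spec a [logic_spec()].
#' @param library list of orthogonal [switch_part()]s (consumed in
#'   order).
#' @param cfg a [design_config()].
#' @param model an [energy_model()].
#' @param linker inter-sensor linker RNA for concatenated switches
#'   (default 9 nt).
#' @param screen_threshold crosstalk flagging threshold passed to
#'   [screen_netlist()]; candidate designs are re-drawn (with shifted
#'   overhang seeds) until the screen is clean.
#' @param max_design_attempts candidate netlists screened before
#'   giving up.
#' @return An unwired [circuit_netlist()] with the crosstalk screen
#'   attached as attribute \code{"screen"}; apply [wire_inducers()]
#'   and [assign_plasmids()] to complete it.
#' @export
compile_gate <- function(spec, library, cfg = design_config(),
                         model = energy_model(), linker = "AACAACAAC",
                         screen_threshold = -45,
                         max_design_attempts = 8L) {
  need <- switch(spec$circuit,
                 BUFFER = 1L, NOT = 1L, NIMPLY = 1L,
                 OR = 2L, AND = 2L, XOR = 2L, NAND = 2L,
                 stop(sprintf("compile_gate handles single gates; use compile_circuit for %s",
                              spec$circuit), call. = FALSE))
  if (length(library) < need) {
    stop(sprintf("insufficient orthogonal parts: %s needs %d switch(es), library has %d",
                 spec$circuit, need, length(library)), call. = FALSE)
  }
  screened_design(cfg, model, screen_threshold, max_design_attempts,
                  function(cfg_k, build) {
    nl <- compile_gate_impl(spec$circuit, spec, library, cfg_k, build,
                            linker, reporter = spec$outputs[1])
    nl$logic <- spec$circuit
    nl
  }, library)
}

# in-silico candidate selection: build a candidate design, screen it
# for crosstalk, and redraw overhangs (shifted seeds) until clean
screened_design <- function(cfg, model, threshold, max_attempts,
                            builder, library) {
  for (attempt in seq_len(max_attempts)) {
    cfg_k <- cfg
    cfg_k$rng_seed <- cfg$rng_seed + 7919L * (attempt - 1L)
    build <- new_build(library, model)
    nl <- builder(cfg_k, build)
    scr <- screen_netlist(nl, model, threshold = threshold)
    if (scr$n_flags == 0) {
      attr(nl, "screen") <- scr
      return(nl)
    }
  }
  stop(sprintf(
    "design screening failed: crosstalk flags remained after %d candidate designs",
    max_attempts), call. = FALSE)
}

compile_gate_impl <- function(circuit, spec, library, cfg, build, linker,
                              reporter, bits = c("A", "B")) {
  sw <- library
  switch(circuit,
    BUFFER = {
      s1 <- sw[[1]]; s1$reporter <- reporter
      t1 <- build_trigger(build, s1, cfg, bits[1])
      circuit_netlist(
        switches = list(s1), triggers = list(t1),
        edges = edge_row(t1$name, s1$name, "activates", 1L),
        reporters = stats::setNames(reporter, s1$name))
    },
    NOT = {
      s1 <- sw[[1]]; s1$reporter <- reporter
      t1 <- build_trigger(build, s1, cfg, NA_character_)
      t1$operator <- "constitutive"
      a1 <- build_antisense(build, t1, cfg, bits[1])
      circuit_netlist(
        switches = list(s1), triggers = list(t1), antisenses = list(a1),
        edges = rbind(edge_row(t1$name, s1$name, "activates", 1L),
                      edge_row(a1$name, t1$name, "annihilates")),
        reporters = stats::setNames(reporter, s1$name))
    },
    NIMPLY = {
      s1 <- sw[[1]]; s1$reporter <- reporter
      t1 <- build_trigger(build, s1, cfg, bits[1])
      a1 <- build_antisense(build, t1, cfg, bits[2])
      circuit_netlist(
        switches = list(s1), triggers = list(t1), antisenses = list(a1),
        edges = rbind(edge_row(t1$name, s1$name, "activates", 1L),
                      edge_row(a1$name, t1$name, "annihilates")),
        reporters = stats::setNames(reporter, s1$name))
    },
    OR = ,
    AND = {
      logic <- if (circuit == "AND") "AND" else "OR"
      csw <- concatenated_switch(sw[1:2], linker_between_sensors = linker,
                                 reporter = reporter, logic = logic)
      t1 <- build_trigger(build, sw[[1]], cfg, bits[1])
      t2 <- build_trigger(build, sw[[2]], cfg, bits[2])
      circuit_netlist(
        switches = list(csw), triggers = list(t1, t2),
        edges = rbind(edge_row(t1$name, csw$name, "activates", 1L),
                      edge_row(t2$name, csw$name, "activates", 2L)),
        reporters = stats::setNames(reporter, csw$name))
    },
    XOR = ,
    NAND = {
      csw <- concatenated_switch(sw[1:2], linker_between_sensors = linker,
                                 reporter = reporter, logic = "OR")
      # input A induces trigger 1 and antisense 2; input B induces
      # trigger 2 and antisense 1
      t1 <- build_trigger(build, sw[[1]], cfg, bits[1])
      t2 <- build_trigger(build, sw[[2]], cfg, bits[2])
      a1 <- build_antisense(build, t1, cfg, bits[2])
      a2 <- build_antisense(build, t2, cfg, bits[1])
      if (circuit == "NAND") {
        t1$operator <- "constitutive"; t1$input_bit <- NA_character_
        t2$operator <- "constitutive"; t2$input_bit <- NA_character_
      }
      circuit_netlist(
        switches = list(csw), triggers = list(t1, t2),
        antisenses = list(a1, a2),
        edges = rbind(edge_row(t1$name, csw$name, "activates", 1L),
                      edge_row(t2$name, csw$name, "activates", 2L),
                      edge_row(a1$name, t1$name, "annihilates"),
                      edge_row(a2$name, t2$name, "annihilates")),
        reporters = stats::setNames(reporter, csw$name))
    },
    stop("unreachable")
  )
}

#' Compile a two-output arithmetic circuit into a netlist
#'
#' Binary calculators are compositions of the single gates on shared
#' inputs: half adder = XOR (SUM) + AND (CARRY); half subtractor = XOR
#' (DIFFERENCE) + NIMPLY (BORROW); Feynman (controlled-NOT) gate = XOR
#' (Q) + BUFFER (P).  Sub-gates read the same inducers and report on
#' distinct channels.  Single-gate specs are delegated to
#' [compile_gate()].
#'
#' @inheritParams compile_gate
#' @param borrow_convention for the half subtractor computing A - B:
#'   \code{"B_nimply_A"} (default, BORROW = NOT A AND B) or
#'   \code{"A_nimply_B"}.
#' @param buffer_arm_switch 1-based index into \code{library} of the
#'   switch used for the Feynman BUFFER arm (default: the one after the
#'   XOR pair).
#' @return A [circuit_netlist()] with a pairwise crosstalk screen
#'   attached as attribute \code{"screen"}.
#' @export
compile_circuit <- function(spec, library, cfg = design_config(),
                            model = energy_model(), linker = "AACAACAAC",
                            borrow_convention = c("B_nimply_A",
                                                  "A_nimply_B"),
                            buffer_arm_switch = 3L,
                            screen_threshold = -45,
                            max_design_attempts = 8L) {
  borrow_convention <- match.arg(borrow_convention)
  if (!spec$circuit %in% c("HALF_ADDER", "HALF_SUBTRACTOR", "FEYNMAN")) {
    return(compile_gate(spec, library, cfg, model, linker,
                        screen_threshold = screen_threshold,
                        max_design_attempts = max_design_attempts))
  }
  need <- if (spec$circuit == "HALF_ADDER") 4L else 3L
  if (length(library) < need) {
    stop(sprintf("insufficient orthogonal parts: %s needs %d switches, library has %d",
                 spec$circuit, need, length(library)), call. = FALSE)
  }
  if (anyDuplicated(spec$outputs)) {
    stop("reporter collision: sub-gates must report on distinct channels",
         call. = FALSE)
  }
  ch1 <- spec$outputs[1]  # XOR arm (SUM / DIFFERENCE / Q)
  ch2 <- spec$outputs[2]  # AND / NIMPLY / BUFFER arm
  screened_design(cfg, model, screen_threshold, max_design_attempts,
                  function(cfg_k, build) {
    xor_nl <- compile_gate_impl("XOR", spec, library[1:2], cfg_k, build,
                                linker, reporter = ch1)
    second <- switch(spec$circuit,
      HALF_ADDER = {
        compile_gate_impl("AND", spec, library[3:4], cfg_k, build,
                          linker, reporter = ch2)
      },
      HALF_SUBTRACTOR = {
        bits <- if (borrow_convention == "B_nimply_A") c("B", "A")
                else c("A", "B")
        compile_gate_impl("NIMPLY", spec, library[buffer_arm_switch],
                          cfg_k, build, linker, reporter = ch2,
                          bits = bits)
      },
      FEYNMAN = {
        # the BUFFER arm reuses the half-subtractor parts but with a
        # trigger carrying no extended overhangs
        cfg_p <- cfg_k
        cfg_p$trigger_overhang_mode <- "none"
        compile_gate_impl("BUFFER", spec, library[buffer_arm_switch],
                          cfg_p, build, linker, reporter = ch2)
      })
    circuit_netlist(
      switches = c(xor_nl$switches, second$switches),
      triggers = c(xor_nl$triggers, second$triggers),
      antisenses = c(xor_nl$antisenses, second$antisenses),
      edges = rbind(xor_nl$edges, second$edges),
      reporters = c(xor_nl$reporters, second$reporters),
      logic = spec$circuit)
  }, library)
}

#' Pairwise crosstalk screen of a compiled netlist
#'
#' Computes duplex energies between every trigger/antisense and every
#' switch sensor site, and between all trigger-antisense pairs,
#' flagging unintended interactions stronger than the threshold.
#' Interactions that are part of the architecture are exempt: a
#' trigger against its cognate sensor, an antisense against its target
#' trigger, and an antisense against the sensor its target trigger
#' opens (the antisense is sequence-identical to that sensor's
#' stem-bottom strand, so the naive duplex energy against the
#' stem-top is large, but the stem-top is sequestered by the folded
#' hairpin).
#'
#' @param netlist a [circuit_netlist()].
#' @param model an [energy_model()].
#' @param threshold flagging threshold, model units.
#' @return list of [crosstalk_matrix()] results
#'   (\code{trigger_site}, \code{trigger_antisense},
#'   \code{antisense_site}) plus \code{n_flags}.
#' @export
screen_netlist <- function(netlist, model = energy_model(),
                           threshold = -45) {
  sites <- netlist_sites(netlist)
  site_seq <- vapply(sites, function(s) switch_sequence(s$part),
                     character(1))
  tr_seq <- vapply(netlist$triggers, rna_sequence, character(1))
  an_seq <- vapply(netlist$antisenses, rna_sequence, character(1))
  e <- netlist$edges
  act <- e[e$type == "activates", , drop = FALSE]
  ann <- e[e$type == "annihilates", , drop = FALSE]
  # cognate sensor site of each trigger
  trig_site <- stats::setNames(
    match(paste0(act$to, "#", act$sensor), names(sites)), act$from)
  out <- list()
  if (length(tr_seq) > 0) {
    cog <- cbind(match(names(trig_site), names(tr_seq)),
                 unname(trig_site))
    out$trigger_site <- crosstalk_matrix(tr_seq, site_seq, model,
                                         threshold = threshold,
                                         cognate = cog)
  }
  if (length(tr_seq) > 0 && length(an_seq) > 0) {
    cog <- cbind(match(ann$to, names(tr_seq)),
                 match(ann$from, names(an_seq)))
    out$trigger_antisense <- crosstalk_matrix(tr_seq, an_seq, model,
                                              threshold = threshold,
                                              cognate = cog)
  }
  if (length(an_seq) > 0) {
    cog <- cbind(match(ann$from, names(an_seq)),
                 unname(trig_site[ann$to]))
    out$antisense_site <- crosstalk_matrix(an_seq, site_seq, model,
                                           threshold = threshold,
                                           cognate = cog)
  }
  out$n_flags <- sum(vapply(out, function(m) {
    if (is.list(m) && !is.null(m$flag)) sum(m$flag) else 0L
  }, numeric(1)))
  out
}

#' Wire chemical inducers to netlist operators
#'
#' Places transcriptional operators on the trigger and antisense
#' cassettes so that each inducer drives its input bit.  For the XOR
#' architecture this realises the cross-wiring in which one inducer
#' simultaneously induces the trigger of one NIMPLY arm and the
#' antisense of the other (IPTG/lac upstream of T1 and A2, aTc/tet
#' upstream of T2 and A1).  Constitutive species are left untouched.
#'
#' @param netlist a compiled [circuit_netlist()].
#' @param mapping named character vector inducer -> input bit, e.g.
#'   \code{c(IPTG = "A", aTc = "B")}.
#' @param operator_for optional named character vector inducer ->
#'   operator; defaults to lac for IPTG, tet for aTc, the lower-case
#'   inducer name otherwise.
#' @return The netlist with operators assigned and \code{inducer_map} /
#'   \code{input_bits} populated.
#' @export
wire_inducers <- function(netlist, mapping = c(IPTG = "A", aTc = "B"),
                          operator_for = NULL) {
  bits_used <- stats::na.omit(unique(c(
    vapply(netlist$triggers, function(t) t$input_bit %||% NA_character_,
           character(1)),
    vapply(netlist$antisenses, function(a) a$input_bit %||% NA_character_,
           character(1)))))
  missing <- setdiff(bits_used, unname(mapping))
  if (length(missing) > 0) {
    stop(sprintf("inducer mapping does not cover input bit(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  default_ops <- c(IPTG = "lac", aTc = "tet")
  ops <- vapply(names(mapping), function(ind) {
    if (!is.null(operator_for) && ind %in% names(operator_for)) {
      operator_for[[ind]]
    } else if (ind %in% names(default_ops)) {
      default_ops[[ind]]
    } else {
      tolower(ind)
    }
  }, character(1))
  names(ops) <- names(mapping)
  bit_to_op <- stats::setNames(ops, unname(mapping))
  set_op <- function(sp) {
    bit <- sp$input_bit %||% NA_character_
    if (!is.na(bit) && sp$operator != "constitutive") {
      sp$operator <- unname(bit_to_op[[bit]])
    }
    sp
  }
  netlist$triggers <- lapply(netlist$triggers, set_op)
  netlist$antisenses <- lapply(netlist$antisenses, set_op)
  netlist$inducer_map <- ops
  netlist$input_bits <- stats::setNames(unname(mapping), names(mapping))
  netlist
}

#' Assign plasmid copy levels to netlist species
#'
#' Default architecture: switches from a low-copy plasmid, triggers
#' from a medium-copy plasmid and antisenses from a high-copy plasmid,
#' so that antisense excess drives strong repression.
#'
#' @param netlist a [circuit_netlist()].
#' @param levels default level per role.
#' @param override named character vector species -> level applied
#'   last.
#' @return The netlist with \code{plasmids} populated.
#' @export
assign_plasmids <- function(netlist,
                            levels = c(switch = "low", trigger = "medium",
                                       antisense = "high"),
                            override = character(0)) {
  p <- c(
    stats::setNames(rep(levels[["switch"]], length(netlist$switches)),
                    names(netlist$switches)),
    stats::setNames(rep(levels[["trigger"]], length(netlist$triggers)),
                    names(netlist$triggers)),
    stats::setNames(rep(levels[["antisense"]], length(netlist$antisenses)),
                    names(netlist$antisenses)))
  for (nm in names(override)) p[[nm]] <- override[[nm]]
  bad <- setdiff(unique(p), c("low", "medium", "high"))
  if (length(bad) > 0) {
    stop(sprintf("unknown copy level(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  netlist$plasmids <- p
  netlist
}

#' Evaluate a netlist symbolically on Boolean inputs
#'
#' Ignores concentrations entirely: a species is present iff it is
#' constitutive, unwired, or its input bit is TRUE; a trigger is active
#' iff present and no present antisense annihilates it; a sensor is
#' active iff some cognate trigger is active; a switch fires per its
#' sensor logic (OR / AND).  This is the structural truth table implied
#' by the edges alone.
#'
#' @param netlist a compiled [circuit_netlist()].
#' @param inputs named logical vector over input bits, e.g.
#'   \code{c(A = TRUE, B = FALSE)}.
#' @return Named logical vector, one element per reporter channel.
#' @export
eval_netlist_boolean <- function(netlist, inputs) {
  present <- function(sp) {
    if (sp$operator == "constitutive") return(TRUE)
    bit <- sp$input_bit %||% NA_character_
    if (is.na(bit)) return(TRUE)
    isTRUE(inputs[[bit]])
  }
  e <- netlist$edges
  trig_active <- vapply(netlist$triggers, function(t) {
    if (!present(t)) return(FALSE)
    ann <- e$from[e$type == "annihilates" & e$to == t$name]
    !any(vapply(netlist$antisenses[ann], present, logical(1)))
  }, logical(1))
  out <- logical(0)
  for (sw in netlist$switches) {
    n_sensors <- if (inherits(sw, "concatenated_switch")) {
      length(sw$sensors)
    } else {
      1L
    }
    sensor_on <- vapply(seq_len(n_sensors), function(s) {
      trg <- e$from[e$type == "activates" & e$to == sw$name &
                      e$sensor == s]
      any(trig_active[trg])
    }, logical(1))
    logic <- if (inherits(sw, "concatenated_switch")) sw$logic else "OR"
    val <- if (logic == "AND") all(sensor_on) else any(sensor_on)
    ch <- netlist$reporters[[sw$name]] %||% sw$reporter
    out[ch] <- val
  }
  out
}
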
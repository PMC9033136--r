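#' Construct a toehold switch part
#'
#' A toehold switch is a hairpin riboregulator whose stem sequesters the
#' ribosome binding site (RBS) and start codon; a complementary trigger
#' RNA invades the 5' toehold and opens the stem, restoring translation.
#' The part is stored as its anatomical segments, all 5'->3' RNA.  The
#' full transcript is \code{toehold + stem_bottom + loop + stem_top +
#' linker}; the trigger-binding (sensing) domain is \code{toehold +
#' stem_bottom}.
#'
#' @param name part identifier.
#' @param toehold_seq single-stranded 5' toehold.
#' @param stem_bottom 5'-side stem strand (continues the sensing domain).
#' @param stem_top 3'-side stem strand sequestering the RBS region;
#'   reverse complement of \code{stem_bottom} up to designed mismatches.
#' @param loop_seq hairpin loop containing the RBS motif exactly once.
#' @param linker_seq post-stem region joining the hairpin to the
#'   reporter reading frame; carries the start codon.
#' @param start_codon_offset 0-based index of the start codon within
#'   \code{linker_seq}.
#' @param reporter reporter channel tag (e.g. \code{"green"}).
#' @return An object of class \code{switch_part}.
#' @seealso [validate_switch()], [make_switch_library()]
#' @export
switch_part <- function(name, toehold_seq, stem_bottom, stem_top, loop_seq,
                        linker_seq, start_codon_offset = 0L,
                        reporter = "green") {
  fields <- c(toehold_seq = toehold_seq, stem_bottom = stem_bottom,
              stem_top = stem_top, loop_seq = loop_seq,
              linker_seq = linker_seq)
  for (f in names(fields)) {
    if (nchar(fields[[f]]) == 0) {
      stop(sprintf("switch '%s': %s must be non-empty", name, f),
           call. = FALSE)
    }
    encode_rna(fields[[f]])  # alphabet check
  }
  structure(
    list(name = name, toehold_seq = toupper(toehold_seq),
         stem_bottom = toupper(stem_bottom), stem_top = toupper(stem_top),
         loop_seq = toupper(loop_seq), linker_seq = toupper(linker_seq),
         start_codon_offset = as.integer(start_codon_offset),
         reporter = reporter),
    class = "switch_part"
  )
}

#' @export
print.switch_part <- function(x, ...) {
  cat(sprintf("toehold switch '%s' (reporter %s)\n", x$name, x$reporter))
  cat(sprintf("  toehold %d nt | stem %d bp | loop %d nt | linker %d nt\n",
              nchar(x$toehold_seq), nchar(x$stem_bottom),
              nchar(x$loop_seq), nchar(x$linker_seq)))
  invisible(x)
}

#' Full transcript sequence of a switch part
#' @param part a [switch_part()].
#' @return RNA string, 5'->3'.
#' @export
switch_sequence <- function(part) {
  paste0(part$toehold_seq, part$stem_bottom, part$loop_seq, part$stem_top,
         part$linker_seq)
}

#' Trigger-binding (sensing) domain of a switch
#' @param part a [switch_part()].
#' @return RNA string \code{toehold + stem_bottom}.
#' @export
sensing_domain <- function(part) {
  paste0(part$toehold_seq, part$stem_bottom)
}

# declared target structure of a switch: stem paired, all else
# single-stranded.  Returns a 0-based pair matrix in full-transcript
# coordinates.
switch_target_structure <- function(part) {
  t_len <- nchar(part$toehold_seq)
  s_len <- nchar(part$stem_bottom)
  l_len <- nchar(part$loop_seq)
  i <- t_len + seq_len(s_len) - 1L
  j <- t_len + s_len + l_len + s_len - seq_len(s_len)
  cbind(i, j)
}

#' Validate a switch part against its structural invariants
#'
#' Checks, with one report row per invariant: (1) alphabet is A/C/G/U;
#' (2) \code{stem_top} is the reverse complement of \code{stem_bottom}
#' up to the configured number of designed mismatches; (3) the loop
#' contains the RBS motif exactly once; (4) the toehold is single-
#' stranded: unpaired in the declared target structure and free of
#' stacked helices in its own predicted MFE fold (isolated breathing
#' pairs are tolerated).
#'
#' @param part a [switch_part()].
#' @param config a [part_config()].
#' @param model an [energy_model()] for the toehold fold check.
#' @return A list with \code{checks} (data.frame of check, pass,
#'   detail) and \code{valid} (all passed).
#' @export
validate_switch <- function(part, config = part_config(),
                            model = energy_model()) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }

  seqs <- c(part$toehold_seq, part$stem_bottom, part$stem_top,
            part$loop_seq, part$linker_seq)
  alpha_ok <- all(grepl("^[ACGU]+$", seqs))
  add("alphabet", alpha_ok, if (!alpha_ok) "non-ACGU characters" else "")

  rc <- rna_revcomp(part$stem_bottom)
  mism <- if (nchar(rc) == nchar(part$stem_top)) {
    sum(strsplit(rc, "")[[1]] != strsplit(part$stem_top, "")[[1]])
  } else {
    Inf
  }
  stem_ok <- is.finite(mism) && mism <= config$allowed_stem_mismatches
  add("stem_complementarity", stem_ok,
      sprintf("%s mismatches (allowed %d)",
              ifelse(is.finite(mism), mism, "length"),
              config$allowed_stem_mismatches))

  n_rbs <- count_occurrences(part$loop_seq, config$rbs)
  add("rbs_single", n_rbs == 1L,
      sprintf("RBS '%s' found %d time(s) in loop", config$rbs, n_rbs))

  tgt <- switch_target_structure(part)
  t_len <- nchar(part$toehold_seq)
  in_target <- any(c(tgt[, 1], tgt[, 2]) < t_len)
  # isolated pairs are tolerated as breathing; a stacked helix in the
  # toehold's own MFE is real self-structure
  toe_fold <- fold_mfe(part$toehold_seq, model)
  stacked <- FALSE
  if (nrow(toe_fold$pairs) > 1) {
    key <- paste(toe_fold$pairs[, 1], toe_fold$pairs[, 2])
    stacked <- any(paste(toe_fold$pairs[, 1] + 1,
                         toe_fold$pairs[, 2] - 1) %in% key)
  }
  toe_ok <- !in_target && !stacked
  add("toehold_single_stranded", toe_ok,
      if (in_target) "toehold paired in declared target"
      else if (stacked) "stacked helix in toehold MFE"
      else "")

  checks <- do.call(rbind, checks)
  list(checks = checks, valid = all(checks$pass))
}

# non-overlapping occurrence count of a motif in a string
count_occurrences <- function(x, motif) {
  length(gregexpr(motif, x, fixed = TRUE)[[1]][
    gregexpr(motif, x, fixed = TRUE)[[1]] > 0])
}

#' Part-level validation configuration
#'
#' @param rbs RBS motif required exactly once in the switch loop.
#' @param allowed_stem_mismatches designed mismatches tolerated between
#'   stem strands.
#' @return A list of class \code{part_config}.
#' @export
part_config <- function(rbs = "AGGAGG", allowed_stem_mismatches = 0L) {
  structure(list(rbs = rbs,
                 allowed_stem_mismatches = as.integer(allowed_stem_mismatches)),
            class = "part_config")
}

#' Construct a trigger RNA
#'
#' A trans-acting RNA whose core is complementary to a switch sensing
#' domain (toehold + stem bottom); optional 5'/3' overhangs provide a
#' thermodynamic handle for antisense capture, and single-nucleotide
#' bulges at the overhang-core junctions interrupt long duplexes.
#'
#' @param name identifier (T1, T2, ...).
#' @param core_seq switch-binding core, 5'->3'.
#' @param overhang5,overhang3 overhang sequences (may be empty).
#' @param bulges data.frame with columns \code{position} (0-based index
#'   into the assembled full sequence) and \code{base}.
#' @param operator transcriptional operator gating this species: one of
#'   \code{"lac"}, \code{"tet"}, \code{"none"}, \code{"constitutive"}.
#' @param cognate_switch optional name of the switch this trigger opens.
#' @return An object of class \code{trigger_rna}.
#' @export
trigger_rna <- function(name, core_seq, overhang5 = "", overhang3 = "",
                        bulges = empty_bulges(), operator = "none",
                        cognate_switch = NULL) {
  stopifnot(nchar(core_seq) > 0)
  for (s in c(core_seq, overhang5, overhang3)) {
    if (nchar(s) > 0) encode_rna(s)
  }
  operator <- match.arg(operator, c("lac", "tet", "none", "constitutive"))
  structure(
    list(name = name, core_seq = toupper(core_seq),
         overhang5 = toupper(overhang5), overhang3 = toupper(overhang3),
         bulges = bulges, operator = operator,
         cognate_switch = cognate_switch),
    class = "trigger_rna"
  )
}

#' Construct an antisense RNA
#'
#' An RNA complementary to a trigger core that annihilates the trigger
#' by direct hybridization or strand displacement (the NOT arm of a
#' NIMPLY gate).  Overhangs extend pairing into the trigger's overhangs;
#' an empty bulge table is a "full-match" antisense.
#'
#' @param name identifier (A1, A2, ...).
#' @param target_trigger name of the trigger this antisense annihilates.
#' @inheritParams trigger_rna
#' @return An object of class \code{antisense_rna}.
#' @export
antisense_rna <- function(name, target_trigger, core_seq, overhang5 = "",
                          overhang3 = "", bulges = empty_bulges(),
                          operator = "none") {
  stopifnot(nchar(core_seq) > 0)
  for (s in c(core_seq, overhang5, overhang3)) {
    if (nchar(s) > 0) encode_rna(s)
  }
  operator <- match.arg(operator, c("lac", "tet", "none", "constitutive"))
  structure(
    list(name = name, target_trigger = target_trigger,
         core_seq = toupper(core_seq), overhang5 = toupper(overhang5),
         overhang3 = toupper(overhang3), bulges = bulges,
         operator = operator),
    class = "antisense_rna"
  )
}

#' @export
print.trigger_rna <- function(x, ...) {
  cat(sprintf("trigger '%s': core %d nt, 5'oh %d nt, 3'oh %d nt, %d bulge(s), operator %s\n",
              x$name, nchar(x$core_seq), nchar(x$overhang5),
              nchar(x$overhang3), nrow(x$bulges), x$operator))
  invisible(x)
}

#' @export
print.antisense_rna <- function(x, ...) {
  cat(sprintf("antisense '%s' -> %s: core %d nt, 5'oh %d nt, 3'oh %d nt, %s, operator %s\n",
              x$name, x$target_trigger, nchar(x$core_seq),
              nchar(x$overhang5), nchar(x$overhang3),
              if (nrow(x$bulges) == 0) "full match"
              else sprintf("%d bulge(s)", nrow(x$bulges)),
              x$operator))
  invisible(x)
}

empty_bulges <- function() {
  data.frame(position = integer(0), base = character(0),
             stringsAsFactors = FALSE)
}

#' Assemble the full sequence of a trigger or antisense RNA
#'
#' The full sequence is \code{overhang5 + [bulge] + core + [bulge] +
#' overhang3}, with bulge bases inserted at the positions recorded in
#' the part's bulge table.
#'
#' @param x a [trigger_rna()] or [antisense_rna()].
#' @return RNA string, 5'->3'.
#' @export
rna_sequence <- function(x) {
  UseMethod("rna_sequence")
}

#' @export
rna_sequence.trigger_rna <- function(x) assemble_full(x)

#' @export
rna_sequence.antisense_rna <- function(x) assemble_full(x)

#' @export
rna_sequence.switch_part <- function(x) switch_sequence(x)

#' @export
rna_sequence.character <- function(x) toupper(x)

assemble_full <- function(x) {
  backbone <- paste0(x$overhang5, x$core_seq, x$overhang3)
  chars <- strsplit(backbone, "")[[1]]
  if (nrow(x$bulges) > 0) {
    b <- x$bulges[order(x$bulges$position), , drop = FALSE]
    for (k in seq_len(nrow(b))) {
      pos <- b$position[k]  # 0-based index in the FULL sequence
      chars <- append(chars, b$base[k], after = pos)
    }
  }
  paste(chars, collapse = "")
}

#' Disassemble a full trigger/antisense sequence into components
#'
#' Inverse of the assembly rule: strips the recorded bulge bases and
#' splits the backbone into 5' overhang, core and 3' overhang.
#'
#' @param full assembled RNA string.
#' @param overhang5_len,core_len component lengths (nt).
#' @param bulges bulge table as stored on the part.
#' @return list(overhang5, core_seq, overhang3, bulges).
#' @export
disassemble_rna <- function(full, overhang5_len, core_len,
                            bulges = empty_bulges()) {
  chars <- strsplit(full, "")[[1]]
  if (nrow(bulges) > 0) {
    b <- bulges[order(bulges$position, decreasing = TRUE), , drop = FALSE]
    for (k in seq_len(nrow(b))) {
      stopifnot(chars[b$position[k] + 1] == b$base[k])
      chars <- chars[-(b$position[k] + 1)]
    }
  }
  backbone <- paste(chars, collapse = "")
  list(
    overhang5 = substr(backbone, 1, overhang5_len),
    core_seq = substr(backbone, overhang5_len + 1, overhang5_len + core_len),
    overhang3 = substr(backbone, overhang5_len + core_len + 1,
                       nchar(backbone)),
    bulges = bulges[order(bulges$position), , drop = FALSE]
  )
}

#' Construct a concatenated multi-sensor switch
#'
#' Joins two or more orthogonal switch sensors with a short linker into
#' a single transcript ahead of one reporter.  With \code{logic = "OR"}
#' either cognate trigger activates the reporter (the concatenated OR
#' gate); \code{logic = "AND"} models a black-box two-trigger sensor
#' that requires both triggers bound.
#'
#' @param sensors list of [switch_part()] (length >= 2).
#' @param linker_between_sensors inter-sensor linker RNA (default 9 nt).
#' @param reporter reporter channel tag.
#' @param logic \code{"OR"} or \code{"AND"}.
#' @param name identifier.
#' @return An object of class \code{concatenated_switch}.
#' @export
concatenated_switch <- function(sensors, linker_between_sensors = "AACAACAAC",
                                reporter = "green", logic = c("OR", "AND"),
                                name = NULL) {
  logic <- match.arg(logic)
  if (length(sensors) < 2) {
    stop("a concatenated switch needs at least 2 sensors", call. = FALSE)
  }
  encode_rna(linker_between_sensors)
  if (is.null(name)) {
    name <- paste(vapply(sensors, function(s) s$name, character(1)),
                  collapse = "+")
  }
  structure(
    list(name = name, sensors = sensors,
         linker_between_sensors = toupper(linker_between_sensors),
         reporter = reporter, logic = logic),
    class = "concatenated_switch"
  )
}

#' @export
print.concatenated_switch <- function(x, ...) {
  cat(sprintf("concatenated switch '%s' (%s, %d sensors, %d-nt linker, reporter %s)\n",
              x$name, x$logic, length(x$sensors),
              nchar(x$linker_between_sensors), x$reporter))
  invisible(x)
}

#' @export
rna_sequence.concatenated_switch <- function(x) {
  seqs <- vapply(x$sensors, switch_sequence, character(1))
  paste(seqs, collapse = x$linker_between_sensors)
}

#' Assemble a circuit netlist
#'
#' The netlist is the compiled representation of a logic circuit:
#' species (switches, triggers, antisenses), typed edges (a trigger
#' \emph{activates} a switch sensor; an antisense \emph{annihilates} a
#' trigger), plasmid copy levels, inducer-to-operator wiring and
#' reporter channels.
#'
#' @param switches list of [switch_part()] / [concatenated_switch()].
#' @param triggers list of [trigger_rna()].
#' @param antisenses list of [antisense_rna()].
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{type} (\code{activates}/\code{annihilates}) and
#'   \code{sensor} (sensor index within the target switch; NA for
#'   annihilation edges).
#' @param plasmids named character vector species -> copy level
#'   (\code{low}/\code{medium}/\code{high}).
#' @param inducer_map named character vector inducer -> operator.
#' @param reporters named character vector switch -> channel.
#' @param logic name of the compiled logic function, if any.
#' @return An object of class \code{circuit_netlist}.
#' @export
circuit_netlist <- function(switches, triggers = list(),
                            antisenses = list(), edges = NULL,
                            plasmids = character(0),
                            inducer_map = character(0),
                            reporters = character(0), logic = NA_character_) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        type = character(0), sensor = integer(0),
                        stringsAsFactors = FALSE)
  }
  names(switches) <- vapply(switches, function(x) x$name, character(1))
  names(triggers) <- vapply(triggers, function(x) x$name, character(1))
  names(antisenses) <- vapply(antisenses, function(x) x$name, character(1))
  nl <- structure(
    list(switches = switches, triggers = triggers, antisenses = antisenses,
         edges = edges, plasmids = plasmids, inducer_map = inducer_map,
         reporters = reporters, logic = logic),
    class = "circuit_netlist"
  )
  validate_netlist(nl)
  nl
}

validate_netlist <- function(nl) {
  species <- c(names(nl$switches), names(nl$triggers), names(nl$antisenses))
  e <- nl$edges
  missing <- setdiff(unique(c(e$from, e$to)), species)
  if (length(missing) > 0) {
    stop(sprintf("netlist edge references unknown species: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ann <- e[e$type == "annihilates", , drop = FALSE]
  for (k in seq_len(nrow(ann))) {
    a <- nl$antisenses[[ann$from[k]]]
    if (is.null(a)) {
      stop(sprintf("annihilation edge from non-antisense '%s'", ann$from[k]),
           call. = FALSE)
    }
    if (a$target_trigger != ann$to[k]) {
      stop(sprintf("antisense '%s' annihilates '%s' but is declared against '%s'",
                   a$name, ann$to[k], a$target_trigger), call. = FALSE)
    }
  }
  invisible(nl)
}

#' @export
print.circuit_netlist <- function(x, ...) {
  cat(sprintf("circuit netlist%s: %d switch(es), %d trigger(s), %d antisense(s), %d edge(s)\n",
              if (is.na(x$logic)) "" else sprintf(" [%s]", x$logic),
              length(x$switches), length(x$triggers), length(x$antisenses),
              nrow(x$edges)))
  if (length(x$inducer_map) > 0) {
    cat("  inducers:", paste(names(x$inducer_map), x$inducer_map,
                             sep = "->", collapse = ", "), "\n")
  }
  if (length(x$plasmids) > 0) {
    cat("  plasmids:", paste(names(x$plasmids), x$plasmids,
                             sep = ":", collapse = ", "), "\n")
  }
  invisible(x)
}
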
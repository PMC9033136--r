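#' Design configuration for trigger and antisense derivation
#'
#' Encodes the overhang/bulge design space explored for NIMPLY-gate
#' components.  Two named presets capture the two design generations:
#' \describe{
#'   \item{\code{"initial"}}{15-nt overhangs on both ends of trigger and
#'     antisense, with a single-nucleotide bulge between every overhang
#'     and the core.}
#'   \item{\code{"optimized"}}{3'-only overhang on triggers, 5'-only
#'     overhang on antisenses, and bulge-free ("full match") antisenses
#'     -- the variant combination with the best measured performance.}
#' }
#'
#' @param preset \code{"optimized"} (default) or \code{"initial"}.
#' @param trigger_overhang_mode,antisense_overhang_mode one of
#'   \code{"both"}, \code{"five_prime_only"}, \code{"three_prime_only"},
#'   \code{"none"}; overrides the preset.
#' @param overhang_len overhang length in nt (default 15).
#' @param trigger_bulge,antisense_bulge \code{"single_nt"} or
#'   \code{"none"}; overrides the preset.
#' @param loop_expansion extra nt added to the switch hairpin loop.
#' @param accessibility_min minimum fraction of overhang bases unpaired
#'   in the predicted MFE of the assembled species.
#' @param crosstalk_max duplex-energy threshold (model units) against
#'   avoid-list species; candidate overhangs must stay above (weaker
#'   than) this.
#' @param max_iter maximum rejection-sampling draws per overhang.
#' @param rng_seed integer seed making designs reproducible.
#' @return An object of class \code{design_config}.
#' @export
design_config <- function(preset = c("optimized", "initial"),
                          trigger_overhang_mode = NULL,
                          antisense_overhang_mode = NULL,
                          overhang_len = 15L,
                          trigger_bulge = NULL,
                          antisense_bulge = NULL,
                          loop_expansion = 0L,
                          accessibility_min = 0.8,
                          crosstalk_max = -25,
                          max_iter = 10000L,
                          rng_seed = 1L) {
  preset <- match.arg(preset)
  defaults <- if (preset == "optimized") {
    list(tmode = "three_prime_only", amode = "five_prime_only",
         tbulge = "single_nt", abulge = "none")
  } else {
    list(tmode = "both", amode = "both",
         tbulge = "single_nt", abulge = "single_nt")
  }
  modes <- c("both", "five_prime_only", "three_prime_only", "none")
  bulges <- c("single_nt", "none")
  tmode <- match.arg(trigger_overhang_mode %||% defaults$tmode, modes)
  amode <- match.arg(antisense_overhang_mode %||% defaults$amode, modes)
  tbulge <- match.arg(trigger_bulge %||% defaults$tbulge, bulges)
  abulge <- match.arg(antisense_bulge %||% defaults$abulge, bulges)
  stopifnot(overhang_len >= 0, loop_expansion >= 0)
  structure(
    list(preset = preset, trigger_overhang_mode = tmode,
         antisense_overhang_mode = amode,
         overhang_len = as.integer(overhang_len),
         trigger_bulge = tbulge, antisense_bulge = abulge,
         loop_expansion = as.integer(loop_expansion),
         accessibility_min = accessibility_min,
         crosstalk_max = crosstalk_max, max_iter = as.integer(max_iter),
         rng_seed = as.integer(rng_seed)),
    class = "design_config"
  )
}

# run code with a private, restored RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

random_rna <- function(n, alphabet = RNA_BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Search for an accessible, low-crosstalk overhang sequence
#'
#' Rejection sampling of random sequences, scored first for
#' accessibility (the overhang must stay mostly unpaired in the
#' predicted MFE of its sequence context) and then for crosstalk
#' against an avoid-list.  Deterministic for a given seed.
#'
#' @param length overhang length (nt); 0 returns "".
#' @param context list with elements \code{before} and \code{after}:
#'   the sequences flanking the overhang in the assembled species.
#' @param model an [energy_model()].
#' @param seed integer seed.
#' @param avoid character vector of sequences the overhang must not
#'   hybridize with (duplex energy above \code{crosstalk_max}).
#' @param accessibility_min minimum unpaired fraction of the overhang.
#' @param crosstalk_max duplex-energy threshold, model units.
#' @param max_iter maximum draws before failing.
#' @return RNA string of the requested length.
#' @export
generate_overhang <- function(length, context = list(before = "", after = ""),
                              model = energy_model(), seed = 1L,
                              avoid = character(0),
                              accessibility_min = 0.8, crosstalk_max = -25,
                              max_iter = 10000L) {
  if (length == 0) return("")
  before <- context$before %||% ""
  after <- context$after %||% ""
  with_seed(seed, {
    best <- NULL
    best_acc <- -Inf
    for (iter in seq_len(max_iter)) {
      cand <- random_rna(length)
      full <- paste0(before, cand, after)
      region <- c(nchar(before), nchar(before) + length)
      acc <- accessibility(full, region, model)
      if (acc > best_acc) {
        best <- cand
        best_acc <- acc
      }
      if (acc < accessibility_min) next
      ok <- TRUE
      for (av in avoid) {
        if (duplex_energy(cand, av, model)$energy < crosstalk_max) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(cand)
    }
    stop(sprintf(
      "overhang search failed after %d draws (best accessibility %.2f, best candidate %s)",
      max_iter, best_acc, best), call. = FALSE)
  })
}

# bulge base rule: the alphabetically first base that cannot pair
# (Watson-Crick or GU) with the base it faces across the cognate
# duplex; "A" when there is no facing base.
choose_bulge_base <- function(facing = NA_character_) {
  if (is.na(facing) || !nzchar(facing)) return("A")
  for (b in RNA_BASES) {
    if (!can_pair(b, facing)) return(b)
  }
  "A"  # unreachable: no base pairs with all four
}

# bulge table for a trigger/antisense given component lengths and
# per-junction bulge bases (NA = no bulge at that junction)
junction_bulges <- function(o5_len, core_len, base5 = NA, base3 = NA) {
  b <- empty_bulges()
  if (!is.na(base5)) {
    b <- rbind(b, data.frame(position = o5_len, base = base5,
                             stringsAsFactors = FALSE))
  }
  if (!is.na(base3)) {
    pos <- o5_len + (!is.na(base5)) + core_len
    b <- rbind(b, data.frame(position = as.integer(pos), base = base3,
                             stringsAsFactors = FALSE))
  }
  b
}

#' Derive a trigger RNA for a switch
#'
#' The trigger core is the reverse complement of the switch sensing
#' domain (toehold + stem bottom), so that the trigger invades the
#' toehold and fully opens the stem.  Overhangs are attached per the
#' configured mode and screened for accessibility and crosstalk; with
#' \code{trigger_bulge = "single_nt"} one bulge nucleotide is inserted
#' between each present overhang and the core.
#'
#' @param switch a [switch_part()].
#' @param cfg a [design_config()].
#' @param model an [energy_model()].
#' @param avoid extra sequences the overhangs must not hybridize with
#'   (e.g. the other switches of a circuit).
#' @param name trigger name (default derived from the switch).
#' @param operator transcriptional operator for the species.
#' @return A [trigger_rna()]; the predicted trigger-switch duplex is
#'   checked to cover the entire sensing domain.
#' @export
derive_trigger <- function(switch, cfg = design_config(),
                           model = energy_model(), avoid = character(0),
                           name = NULL, operator = "none") {
  core <- rna_revcomp(sensing_domain(switch))
  name <- name %||% paste0("T_", switch$name)
  mode <- cfg$trigger_overhang_mode
  len <- cfg$overhang_len
  switch_seq <- switch_sequence(switch)
  avoid_all <- c(switch_seq, avoid)
  o5 <- ""
  o3 <- ""
  if (mode %in% c("both", "five_prime_only") && len > 0) {
    o5 <- generate_overhang(len, list(before = "", after = ""), model,
                            seed = cfg$rng_seed + 101L, avoid = avoid_all,
                            accessibility_min = cfg$accessibility_min,
                            crosstalk_max = cfg$crosstalk_max,
                            max_iter = cfg$max_iter)
  }
  if (mode %in% c("both", "three_prime_only") && len > 0) {
    o3 <- generate_overhang(len, list(before = "", after = ""),
                            model, seed = cfg$rng_seed + 211L,
                            avoid = avoid_all,
                            accessibility_min = cfg$accessibility_min,
                            crosstalk_max = cfg$crosstalk_max,
                            max_iter = cfg$max_iter)
  }
  bulge5 <- bulge3 <- NA_character_
  if (cfg$trigger_bulge == "single_nt") {
    # facing base at the 5' junction: first loop base of the switch
    # (the duplex would extend into the loop there); no facing base at
    # the 3' junction (upstream of the switch 5' end)
    if (nchar(o5) > 0) {
      bulge5 <- choose_bulge_base(substr(switch$loop_seq, 1, 1))
    }
    if (nchar(o3) > 0) bulge3 <- choose_bulge_base(NA)
  }
  trig <- trigger_rna(name, core_seq = core, overhang5 = o5, overhang3 = o3,
                      bulges = junction_bulges(nchar(o5), nchar(core),
                                               bulge5, bulge3),
                      operator = operator, cognate_switch = switch$name)
  # the trigger must fully open the stem: every sensing-domain position
  # of the switch paired in the predicted trigger-switch duplex
  dx <- duplex_energy(rna_sequence(trig), switch_seq, model)
  sensing_idx <- seq.int(0, nchar(sensing_domain(switch)) - 1)
  if (!all(sensing_idx %in% dx$pairs[, 2])) {
    stop(sprintf(
      "design search failed: trigger '%s' does not fully open switch '%s'",
      name, switch$name), call. = FALSE)
  }
  trig
}

#' Derive an antisense RNA against a trigger
#'
#' The antisense core is the reverse complement of the trigger core;
#' overhangs extend pairing into the trigger's own overhangs, providing
#' the thermodynamic driving force that shifts the equilibrium from
#' trigger-switch binding to trigger-antisense binding.  Where the
#' trigger has a cognate overhang the antisense overhang is its reverse
#' complement (proximal portion); otherwise it is searched de novo.
#' With \code{antisense_bulge = "none"} the result is a full-match
#' antisense.
#'
#' @param trigger a [trigger_rna()].
#' @param cfg a [design_config()].
#' @param model an [energy_model()].
#' @param avoid sequences a de-novo overhang must not hybridize with.
#' @param name antisense name.
#' @param operator transcriptional operator for the species.
#' @return An [antisense_rna()].
#' @export
derive_antisense <- function(trigger, cfg = design_config(),
                             model = energy_model(), avoid = character(0),
                             name = NULL, operator = "none") {
  core <- rna_revcomp(trigger$core_seq)
  name <- name %||% sub("^T", "A", trigger$name)
  mode <- cfg$antisense_overhang_mode
  len <- cfg$overhang_len
  o5 <- ""
  o3 <- ""
  if (mode %in% c("both", "five_prime_only") && len > 0) {
    # antisense 5' overhang pairs the trigger 3' overhang (proximal part)
    t3 <- trigger$overhang3
    if (nchar(t3) > 0) {
      o5 <- rna_revcomp(substr(t3, 1, min(len, nchar(t3))))
    } else {
      o5 <- generate_overhang(len, list(before = "", after = ""), model,
                              seed = cfg$rng_seed + 307L, avoid = avoid,
                              accessibility_min = cfg$accessibility_min,
                              crosstalk_max = cfg$crosstalk_max,
                              max_iter = cfg$max_iter)
    }
  }
  if (mode %in% c("both", "three_prime_only") && len > 0) {
    # antisense 3' overhang pairs the trigger 5' overhang (proximal part)
    t5 <- trigger$overhang5
    if (nchar(t5) > 0) {
      o3 <- rna_revcomp(substr(t5, max(1, nchar(t5) - len + 1), nchar(t5)))
    } else {
      o3 <- generate_overhang(len, list(before = "", after = ""), model,
                              seed = cfg$rng_seed + 401L, avoid = avoid,
                              accessibility_min = cfg$accessibility_min,
                              crosstalk_max = cfg$crosstalk_max,
                              max_iter = cfg$max_iter)
    }
  }
  bulge5 <- bulge3 <- NA_character_
  if (cfg$antisense_bulge == "single_nt") {
    if (nchar(o5) > 0) {
      f <- substr(trigger$overhang3, 1, 1)
      bulge5 <- choose_bulge_base(if (nzchar(f)) f else NA)
    }
    if (nchar(o3) > 0) {
      t5 <- trigger$overhang5
      f <- if (nchar(t5) > 0) substr(t5, nchar(t5), nchar(t5)) else ""
      bulge3 <- choose_bulge_base(if (nzchar(f)) f else NA)
    }
  }
  antisense_rna(name, target_trigger = trigger$name, core_seq = core,
                overhang5 = o5, overhang3 = o3,
                bulges = junction_bulges(nchar(o5), nchar(core),
                                         bulge5, bulge3),
                operator = operator)
}

#' Expand the hairpin loop of a switch
#'
#' Lengthens the switch loop by \code{delta} nt with inserted bases
#' screened so that the predicted MFE keeps the stem intact, the
#' inserted bases stay unpaired and the RBS motif remains unique.
#' Loop expansion relieves steric crowding of the RBS at the cost of
#' extra leak, and is exposed as a design variant.
#'
#' @param switch a [switch_part()].
#' @param delta nt to add (0 returns the input unchanged).
#' @param seed integer seed.
#' @param model an [energy_model()].
#' @param config a [part_config()] (for the RBS motif).
#' @param max_iter maximum screening draws.
#' @return A [switch_part()] with the longer loop.
#' @export
expand_loop <- function(switch, delta, seed = 1L, model = energy_model(),
                        config = part_config(), max_iter = 1000L) {
  stopifnot(delta >= 0)
  if (delta == 0) return(switch)
  stem_pairs_of <- function(part) {
    mfe <- fold_mfe(switch_sequence(part), model)
    tgt <- switch_target_structure(part)
    key <- function(m) paste(m[, 1], m[, 2])
    sum(key(mfe$pairs) %in% key(tgt))
  }
  ref_stem <- stem_pairs_of(switch)
  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      ins <- random_rna(delta, alphabet = c("A", "C"))
      cand <- switch
      cand$loop_seq <- paste0(switch$loop_seq, ins)
      if (count_occurrences(cand$loop_seq, config$rbs) != 1L) next
      if (stem_pairs_of(cand) < ref_stem) next
      # inserted bases must stay unpaired in the MFE
      mfe <- fold_mfe(switch_sequence(cand), model)
      t_len <- nchar(cand$toehold_seq)
      s_len <- nchar(cand$stem_bottom)
      ins_idx <- t_len + s_len + nchar(switch$loop_seq) + seq_len(delta) - 1L
      if (any(ins_idx %in% c(mfe$pairs[, 1], mfe$pairs[, 2]))) next
      return(cand)
    }
    stop(sprintf("loop expansion search failed after %d draws", max_iter),
         call. = FALSE)
  })
}
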